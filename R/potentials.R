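#' Integrated sphere-point LJ potential
#'
#' Interaction energy between a point particle and a solid sphere of
#' radius `a` filled with LJ material at number density `rho_s`, obtained
#' by integrating the LJ 12-6 pair potential over the sphere volume:
#' \deqn{U_{SP}(r) = \frac{2\rho_s a^3\sigma^6 A_{cs}}{9}\left[
#'   \frac{(5a^6 + 45a^4 r^2 + 63 a^2 r^4 + 15 r^6)\,\sigma^6}
#'        {15 (r^2-a^2)^9} - \frac{1}{(r^2-a^2)^3}\right]}
#' with \eqn{A_{cs} = 24\pi\epsilon}.  The point particle must lie outside
#' the sphere (`r > a`).
#'
#' @param r Center-to-center distance(s); all must exceed the sphere
#'   radius.
#' @param s A [sphere()].
#' @param p An [lj_params()].
#' @return Energy value(s), same length as `r`.
#' @examples
#' sphere_point_potential(4, sphere(a = 2), lj_params())
#' @export
sphere_point_potential <- function(r, s, p = lj_params()) {
  stopifnot(inherits(s, "lj_sphere"), inherits(p, "lj_params"), is.numeric(r))
  a <- s$a
  if (any(!is.finite(r)) || any(r <= a)) {
    overlap_error(min(r), a)
  }
  pref <- 2 * s$rho_s * a^3 * p$sigma^6 * hamaker_cs(p) / 9
  w <- r^2 - a^2
  M <- 5 * a^6 + 45 * a^4 * r^2 + 63 * a^2 * r^4 + 15 * r^6
  pref * (M * p$sigma^6 / (15 * w^9) - 1 / w^3)
}

# d U_SP / d r, closed form (used by the quadrature torque oracle).
sphere_point_potential_deriv <- function(r, s, p = lj_params()) {
  a <- s$a
  pref <- 2 * s$rho_s * a^3 * p$sigma^6 * hamaker_cs(p) / 9
  w <- r^2 - a^2
  M <- 5 * a^6 + 45 * a^4 * r^2 + 63 * a^2 * r^4 + 15 * r^6
  Mp <- 90 * a^4 * r + 252 * a^2 * r^3 + 90 * r^5
  pref * (p$sigma^6 * (Mp * w - 18 * r * M) / (15 * w^10) + 6 * r / w^4)
}

# Polynomial pieces shared by the closed-form primitives.
# All work in terms of a2 = a^2, h2 = h^2, u = h2 - a2, s(y) = u + y^2.
gdiff_poly <- function(a2, h2) {
  a4 <- a2 * a2; a6 <- a4 * a2
  h4 <- h2 * h2; h6 <- h4 * h2
  list(
    a6 = a6,
    c2 = 4 * (4 * a6 - 9 * a4 * h2) / 35,
    c3 = (11 * a6 - 9 * a4 * h2 + 63 * a2 * h4) / 105,
    N = 16 * a6 + 216 * a4 * h2 + 378 * a2 * h4 + 105 * h6
  )
}

# Individual terms of the primitive G (equivalently Q) at one endpoint,
# excluding the arctan/log piece.  Returns the term vector so callers can
# estimate the cancellation (condition) of the final sum.
gdiff_terms <- function(y, u, sig6, pol) {
  s <- u + y * y
  rep_terms <- sig6 * c(
    8 * pol$a6 * y / (15 * u * s^8),
    -pol$c2 * y / (u^2 * s^7),
    pol$c3 * y / (u^3 * s^6),
    pol$N * y / (1050 * u^4 * s^5),
    3 * pol$N * y / (2800 * u^5 * s^4),
    pol$N * y / (800 * u^6 * s^3),
    pol$N * y / (640 * u^7 * s^2),
    3 * pol$N * y / (1280 * u^8 * s)
  )
  att_terms <- c(y / (4 * u * s^2), 3 * y / (8 * u^2 * s))
  c(rep_terms, -att_terms)
}

# Endpoint difference of the primitive, D = G(yL) - G(0) ... more
# precisely G(yL,h) - G(y0,h), in double precision, for either sign of
# u = h^2 - a^2 (u != 0).  The arctan (u > 0) and log (u < 0) pieces are
# evaluated in paired form so that no accuracy is lost for well-separated
# endpoints.  Returns c(value, tmax) where tmax is the largest magnitude
# among the summed pieces; tmax / |value| estimates the relative
# cancellation and hence the number of digits lost.
gdiff_double <- function(y0, yL, h, a, sigma) {
  a2 <- a * a; h2 <- h * h
  u <- h2 - a2
  sig6 <- sigma^6
  pol <- gdiff_poly(a2, h2)
  tL <- gdiff_terms(yL, u, sig6, pol)
  t0 <- gdiff_terms(y0, u, sig6, pol)
  coefA <- sig6 * 3 * pol$N / (1280 * u^8) - 3 / (8 * u^2)
  if (u > 0) {
    squ <- sqrt(u)
    atd <- if (y0 * yL > 0) {
      atan((yL - y0) * squ / (u + y0 * yL))
    } else {
      atan(yL / squ) - atan(y0 / squ)
    }
    tail_piece <- coefA * atd / squ
  } else {
    v <- sqrt(-u)
    den <- (v + yL) * (v - y0)
    tail_piece <- coefA * log1p(-2 * v * (yL - y0) / den) / (2 * v)
  }
  pieces <- c(tL, -t0, tail_piece)
  c(value = sum(pieces), tmax = max(abs(pieces)))
}

# Same endpoint difference in MPFR arbitrary precision (C kernel), with
# automatic precision escalation until two evaluations one precision step
# apart agree to ~1e-15 relative.
gdiff_extended <- function(y0, yL, h, a, sigma, cond = NA_real_) {
  prec <- if (is.finite(cond) && cond > 1) {
    as.integer(min(16384, 192 + ceiling(log2(cond))))
  } else 512L
  repeat {
    d1 <- .Call(C_gdiff_mpfr, y0, yL, h, a, sigma, prec)
    d2 <- .Call(C_gdiff_mpfr, y0, yL, h, a, sigma, prec + 64L)
    if (is.finite(d1) && is.finite(d2) &&
        abs(d1 - d2) <= 1e-15 * max(abs(d2), .Machine$double.xmin)) {
      return(d2)
    }
    if (prec >= 16384L) {
      if (is.finite(d2)) return(d2)
      stop("internal error: extended-precision primitive did not converge",
           call. = FALSE)
    }
    prec <- min(16384L, prec * 2L)
  }
}

#' Primitive of the sphere-point integrand along the rod axis
#'
#' The antiderivative \eqn{G(y, h)} whose endpoint difference gives the
#' finite-rod potential when the rod axis passes outside the sphere
#' (`h > a`): `W = C [G(yL) - G(y0)]` with
#' `C = 2 lambda rho_s a^3 sigma^6 A_cs / 9`.  `d G / d y` equals
#' `U_SP(sqrt(y^2 + h^2)) / C * lambda`; every term is odd in `y` and
#' `G(0, h) = 0`.  Exposed mainly for verification; this single-endpoint
#' form is evaluated in plain double precision and loses accuracy close to
#' tangency (`h` near `a`), where [finite_rod_potential()] switches to the
#' extended-precision paired evaluation.
#'
#' @param y Axial coordinate(s) relative to the projection of the sphere
#'   center onto the rod axis.
#' @param h Perpendicular distance from the sphere center to the rod axis;
#'   must exceed the sphere radius.
#' @param s A [sphere()].
#' @param p An [lj_params()].
#' @return Primitive value(s), same length as `y`.
#' @export
g_primitive <- function(y, h, s, p = lj_params()) {
  stopifnot(inherits(s, "lj_sphere"), inherits(p, "lj_params"),
            is.numeric(y), is.numeric(h), length(h) == 1L)
  a <- s$a
  if (!(h > a)) {
    stop("g_primitive() requires h > a; dispatch on the branch first",
         call. = FALSE)
  }
  a2 <- a * a; h2 <- h * h
  u <- h2 - a2
  sig6 <- p$sigma^6
  pol <- gdiff_poly(a2, h2)
  coefA <- sig6 * 3 * pol$N / (1280 * u^8) - 3 / (8 * u^2)
  vapply(y, function(yy) {
    sum(gdiff_terms(yy, u, sig6, pol)) + coefA * atan(yy / sqrt(u)) / sqrt(u)
  }, numeric(1))
}

# Tangent-case primitive (h = a): F(y) = 1/(5 y^5) - (sigma^6/15) *
# (128 a^6 / (17 y^17) + 72 a^4 / (5 y^15) + 108 a^2 / (13 y^13) +
#  15 / (11 y^11)).
tangent_primitive <- function(y, a, sigma) {
  1 / (5 * y^5) - (sigma^6 / 15) * (
    128 * a^6 / (17 * y^17) + 72 * a^4 / (5 * y^15) +
      108 * a^2 / (13 * y^13) + 15 / (11 * y^11)
  )
}

potential_result <- function(W, branch, precision_mode, h, a, L) {
  structure(
    list(W = W, branch = branch, precision_mode = precision_mode,
         h = h, delta = h - a, a = a, L = L),
    class = "rodsphere_potential"
  )
}

#' @export
print.rodsphere_potential <- function(x, ...) {
  cat(sprintf("<rodsphere_potential> W = %.10g  [branch %s, precision %s, h = %g, delta = %g]\n",
              x$W, x$branch, x$precision_mode, x$h, x$delta))
  invisible(x)
}

#' @method as_tibble rodsphere_potential
#' @export
as_tibble.rodsphere_potential <- function(x, ...) {
  tibble::tibble(W = x$W, branch = x$branch, precision_mode = x$precision_mode,
                 h = x$h, delta = x$delta, a = x$a, L = x$L)
}

# Build a local configuration from the axial projection coordinate and the
# perpendicular distance (the natural Cartesian parametrization of the
# sphere center in the rod frame).
config_from_xc_h <- function(x_c, h) {
  local_config(rho = sqrt(x_c^2 + h^2), theta = atan2(h, x_c))
}

#' Integrated finite-rod potential
#'
#' Total interaction energy between a continuum sphere and a finite thin
#' rod, `W = C [G(yL) - G(y0)]` with `C = 2 lambda rho_s a^3 sigma^6
#' A_cs / 9`, dispatching between the three closed-form branches:
#' rod axis outside the sphere (`h > a`, arctan form), axis intersecting
#' the sphere with the rod itself outside (`h < a`, real logarithmic
#' form), and the tangent case (`h = a`, within `tol_tangent`).  An
#' infinite rod (`L = Inf`) is routed to [infinite_rod_potential()],
#' which depends on `h` only.
#'
#' The closed forms contain terms that individually diverge like
#' `(h^2 - a^2)^-8` near tangency while their sum stays finite; whenever
#' the measured cancellation exceeds `cond_max` the endpoint difference is
#' re-evaluated in arbitrary-precision (MPFR) arithmetic and the result is
#' flagged `precision_mode = "extended"`.
#'
#' @param config A [local_config()].
#' @param s A [sphere()].
#' @param r An [rod()].
#' @param p An [lj_params()].
#' @param tol_tangent Half-width of the `|h - a|` window in which the
#'   exact tangent-case closed form is used (default `1e-6 * sigma`).
#' @param cond_max Largest acceptable ratio between the biggest summed
#'   term and the final value before escalating to extended precision.
#' @return A `rodsphere_potential` object with fields `W`, `branch`
#'   (one of `"H_GT_A"`, `"TANGENT"`, `"H_LT_A"`, `"INFINITE_ROD"`),
#'   `precision_mode` (`"standard"` or `"extended"`), `h` and
#'   `delta = h - a`.
#' @examples
#' cfg <- local_config(rho = 12, theta = pi / 6)  # h = 6 < a
#' finite_rod_potential(cfg, sphere(a = 10), rod(L = 5), lj_params())
#' @export
finite_rod_potential <- function(config, s, r, p = lj_params(),
                                 tol_tangent = 1e-6 * p$sigma,
                                 cond_max = 1e6) {
  stopifnot(inherits(config, "local_config"), inherits(s, "lj_sphere"),
            inherits(r, "lj_rod"), inherits(p, "lj_params"))
  if (is.infinite(r$L)) {
    return(infinite_rod_potential(config$h, s, r$lambda, p))
  }
  mind <- min_distance_to_rod(config, r)
  if (!(mind > s$a)) overlap_error(mind, s$a)
  a <- s$a
  h <- config$h
  y <- rod_endpoints_y(config, r)
  y0 <- y[["y0"]]; yL <- y[["yL"]]
  prefC <- 2 * r$lambda * s$rho_s * a^3 * p$sigma^6 * hamaker_cs(p) / 9
  delta <- h - a

  if (abs(delta) <= tol_tangent && y0 * yL > 0) {
    W <- prefC * (tangent_primitive(yL, a, p$sigma) -
                    tangent_primitive(y0, a, p$sigma))
    return(potential_result(W, "TANGENT", "standard", h, a, r$L))
  }

  branch <- if (delta > 0) "H_GT_A" else "H_LT_A"
  est <- gdiff_double(y0, yL, h, a, p$sigma)
  D <- est[["value"]]
  cond <- est[["tmax"]] / abs(D)
  if (is.finite(D) && is.finite(cond) && cond < cond_max) {
    return(potential_result(prefC * D, branch, "standard", h, a, r$L))
  }
  D <- gdiff_extended(y0, yL, h, a, p$sigma, cond = cond)
  W <- prefC * D
  if (!is.finite(W)) {
    stop("internal error: non-finite potential after precision escalation",
         call. = FALSE)
  }
  potential_result(W, branch, "extended", h, a, r$L)
}

#' Integrated infinite-rod potential
#'
#' Interaction energy between a continuum sphere and an infinite thin rod
#' at perpendicular axis-center distance `h`:
#' \deqn{W(h) = \frac{\pi\lambda\rho_s a^3\sigma^6 A_{cs}}{3}\left[
#'  \frac{\sigma^6 (16a^6 + 216a^4h^2 + 378a^2h^4 + 105h^6)}
#'       {640 (h^2-a^2)^{17/2}} - \frac{1}{4 (h^2-a^2)^{5/2}}\right]}
#' Requires `h > a` (for an infinite rod any `h <= a` implies overlap).
#' The bracket is evaluated in a factored, overflow-free form (powers of
#' the dimensionless ratio `a^2/(h^2-a^2)` and a single scaled prefactor)
#' so that very large spheres (e.g. `a = 1e4 sigma`) are handled without
#' intermediate overflow.
#'
#' @param h Perpendicular distance from sphere center to the rod axis.
#' @param s A [sphere()].
#' @param lambda Rod line density.
#' @param p An [lj_params()].
#' @return A `rodsphere_potential` with branch `"INFINITE_ROD"`.
#' @examples
#' infinite_rod_potential(12, sphere(a = 10), lambda = 1, lj_params())
#' @export
infinite_rod_potential <- function(h, s, lambda = 1, p = lj_params()) {
  stopifnot(inherits(s, "lj_sphere"), inherits(p, "lj_params"),
            is.numeric(h), length(h) == 1L, is.numeric(lambda), lambda > 0)
  a <- s$a
  if (!is.finite(h) || h <= a) overlap_error(h, a)
  W <- infinite_rod_bracket(h, a, p$sigma) *
    infinite_rod_prefactor(s, lambda, p)
  potential_result(W, "INFINITE_ROD", "standard", h, a, Inf)
}

infinite_rod_prefactor <- function(s, lambda, p) {
  pi * lambda * s$rho_s * s$a^3 * p$sigma^6 * hamaker_cs(p) / 3
}

# The bracket of W(h) for the infinite rod, as (1 / (4 u^{5/2})) *
# (sigma^6 n(x) / (160 u^3) - 1) with u = h^2 - a^2, x = a^2/u and
# n(x) = 16x^3 + 216x^2(1+x) + 378x(1+x)^2 + 105(1+x)^3  (so that
# N = u^3 n(x)); falls back to log-space when the plain product
# over/underflows.
infinite_rod_bracket <- function(h, a, sigma) {
  u <- h^2 - a^2
  x <- a^2 / u
  xp <- 1 + x                      # h^2 / u
  n <- 16 * x^3 + 216 * x^2 * xp + 378 * x * xp^2 + 105 * xp^3
  B <- sigma^6 * n / (160 * u^3) - 1
  out <- B / (4 * u^2.5)
  if (!is.finite(out)) {
    out <- sign(B) * exp(log(abs(B)) - log(4) - 2.5 * log(u))
  }
  out
}

# Closed-form d W / d h for the infinite rod, in the same factored form:
# dW/dh = pref * h / (4 u^{7/2}) * (sigma^6 (m(x) - 17 n(x)) / (160 u^3) + 5)
# with m(x) = 432 x^2 + 1512 x (1+x) + 630 (1+x)^2.
infinite_rod_dWdh <- function(h, s, lambda = 1, p = lj_params()) {
  a <- s$a
  u <- h^2 - a^2
  x <- a^2 / u
  xp <- 1 + x
  n <- 16 * x^3 + 216 * x^2 * xp + 378 * x * xp^2 + 105 * xp^3
  m <- 432 * x^2 + 1512 * x * xp + 630 * xp^2
  B <- p$sigma^6 * (m - 17 * n) / (160 * u^3) + 5
  out <- infinite_rod_prefactor(s, lambda, p) * h * B / (4 * u^3.5)
  if (!is.finite(out)) {
    out <- sign(B) * exp(log(infinite_rod_prefactor(s, lambda, p)) + log(h) +
                           log(abs(B)) - log(4) - 3.5 * log(u))
  }
  out
}

#' Point-rod potential
#'
#' Integrated LJ 12-6 potential between a point particle and an infinite
#' thin rod at perpendicular distance `h`:
#' \deqn{W(h) = \frac{\lambda\sigma^6 A_{cs}}{16 h^5}
#'   \left(\frac{21}{32}\frac{\sigma^6}{h^6} - 1\right)}
#' This is the `a -> 0` limit (at fixed total sphere mass
#' `rho_s (4\pi/3) a^3 = 1`) of the infinite-rod potential.
#'
#' @param h Perpendicular distance(s), all > 0.
#' @param lambda Rod line density.
#' @param p An [lj_params()].
#' @return Energy value(s).
#' @examples
#' point_rod_potential((21 / 32)^(1 / 6), 1, lj_params())  # ~0 at the crossing
#' @export
point_rod_potential <- function(h, lambda = 1, p = lj_params()) {
  stopifnot(inherits(p, "lj_params"), is.numeric(h))
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("point_rod_potential(): h must be > 0", call. = FALSE)
  }
  lambda * p$sigma^6 * hamaker_cs(p) / (16 * h^5) *
    ((21 / 32) * p$sigma^6 / h^6 - 1)
}
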