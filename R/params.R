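#' Lennard-Jones interaction parameters
#'
#' Bundles the energy and length scales of the LJ 12-6 pair potential.
#' All integrated sphere-rod expressions carry the interaction strength
#' through the derived Hamaker-type constant \eqn{A_{cs} = 24\pi\epsilon},
#' available via [hamaker_cs()]; it is always recomputed from `epsilon`,
#' never stored.
#'
#' @param epsilon Energy scale \eqn{\epsilon > 0} (well depth of the pair
#'   potential), in reduced energy units.
#' @param sigma Length scale \eqn{\sigma > 0} (zero-crossing distance of the
#'   pair potential), in reduced length units.
#'
#' @return An object of class `lj_params`.
#' @examples
#' p <- lj_params()
#' hamaker_cs(p) / pi  # 24 * epsilon
#' @export
lj_params <- function(epsilon = 1, sigma = 1) {
  stopifnot(
    is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon), epsilon > 0,
    is.numeric(sigma), length(sigma) == 1L, is.finite(sigma), sigma > 0
  )
  structure(list(epsilon = as.numeric(epsilon), sigma = as.numeric(sigma)),
            class = "lj_params")
}

#' @rdname lj_params
#' @param p An `lj_params` object.
#' @export
hamaker_cs <- function(p) {
  stopifnot(inherits(p, "lj_params"))
  24 * pi * p$epsilon
}

#' @export
print.lj_params <- function(x, ...) {
  cat(sprintf("<lj_params> epsilon = %g, sigma = %g (A_cs = 24*pi*epsilon = %g)\n",
              x$epsilon, x$sigma, hamaker_cs(x)))
  invisible(x)
}

#' Continuum sphere
#'
#' A solid sphere treated as a uniform three-dimensional continuum of LJ
#' material points.
#'
#' @param a Sphere radius (> 0), in units of length.
#' @param rho_s Number density of material points inside the sphere
#'   (> 0), in units of length^-3.  The reduced-unit convention used
#'   throughout the adhesion analysis is `rho_s = 1` (in sigma^-3).
#'
#' @return An object of class `lj_sphere`.
#' @examples
#' sphere(a = 10)
#' @export
sphere <- function(a, rho_s = 1) {
  stopifnot(
    is.numeric(a), length(a) == 1L, is.finite(a), a > 0,
    is.numeric(rho_s), length(rho_s) == 1L, is.finite(rho_s), rho_s > 0
  )
  structure(list(a = as.numeric(a), rho_s = as.numeric(rho_s)),
            class = "lj_sphere")
}

#' @export
print.lj_sphere <- function(x, ...) {
  cat(sprintf("<sphere> a = %g, rho_s = %g\n", x$a, x$rho_s))
  invisible(x)
}

#' Thin rod
#'
#' A thin rod treated as a one-dimensional material line of LJ points with
#' line number density `lambda`.  The rod has no cross-sectional radius.
#' `L = Inf` denotes an infinite rod; operations that require a finite
#' length (e.g. torques) reject it explicitly.
#'
#' @param L Rod length (>= 0, or `Inf` for an infinite rod), in units of
#'   length.
#' @param lambda Line number density of material points (> 0), in units of
#'   length^-1.  The reduced-unit convention is `lambda = 1` (in sigma^-1).
#'
#' @return An object of class `lj_rod`.
#' @examples
#' rod(L = 5)
#' rod(L = Inf)
#' @export
rod <- function(L, lambda = 1) {
  stopifnot(
    is.numeric(L), length(L) == 1L, !is.na(L), L >= 0,
    is.numeric(lambda), length(lambda) == 1L, is.finite(lambda), lambda > 0
  )
  structure(list(L = as.numeric(L), lambda = as.numeric(lambda)),
            class = "lj_rod")
}

#' @export
print.lj_rod <- function(x, ...) {
  cat(sprintf("<rod> L = %s, lambda = %g\n",
              if (is.infinite(x$L)) "Inf" else format(x$L), x$lambda))
  invisible(x)
}

#' LJ 12-6 pair potential
#'
#' \deqn{U(r) = 4\epsilon\left[(\sigma/r)^{12} - (\sigma/r)^6\right]}
#'
#' @param r Distance(s) between the two point particles; all must be > 0.
#' @param p An [lj_params()] object.
#' @return Energy value(s), same length as `r`.
#' @examples
#' p <- lj_params()
#' lj_pair(1, p)            # 0 at the zero crossing r = sigma
#' lj_pair(2^(1 / 6), p)    # -epsilon at the minimum
#' @export
lj_pair <- function(r, p = lj_params()) {
  stopifnot(inherits(p, "lj_params"), is.numeric(r))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("lj_pair(): all distances must be finite and > 0", call. = FALSE)
  }
  sr6 <- (p$sigma / r)^6
  4 * p$epsilon * (sr6^2 - sr6)
}
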