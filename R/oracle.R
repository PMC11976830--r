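#' Quadrature settings for the numerical oracle
#'
#' The oracle re-computes the sphere-rod interaction by adaptive
#' Gauss-Kronrod quadrature of the defining integrals and is used only for
#' verification; it is orders of magnitude slower than the closed forms.
#'
#' @param rel_tol Relative tolerance requested from the adaptive rule.
#' @param abs_tol Absolute tolerance (energy units).
#' @param max_subdivisions Subdivision limit per panel.
#' @param truncation_length Half-length (in units of length) at which a
#'   pseudo-infinite rod is truncated; the neglected tail decays as the
#'   fifth inverse power of the truncation, so the default is far below
#'   `rel_tol` for all tested configurations.
#' @return A list of class `quadrature_spec`.
#' @export
quadrature_spec <- function(rel_tol = 1e-11, abs_tol = 1e-30,
                            max_subdivisions = 500L,
                            truncation_length = 1e4) {
  stopifnot(rel_tol > 0, abs_tol >= 0, max_subdivisions >= 50,
            truncation_length >= 1e3)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_subdivisions = as.integer(max_subdivisions),
                 truncation_length = truncation_length),
            class = "quadrature_spec")
}

# Integrate f over [lo, hi] splitting at the interior points in `splits`;
# the sphere-rod integrand peaks sharply at the point of closest approach
# (y = 0), so panels are split there.
integrate_panels <- function(f, lo, hi, splits, q) {
  pts <- sort(unique(c(lo, hi, splits[splits > lo & splits < hi])))
  total <- 0
  err <- 0
  for (i in seq_len(length(pts) - 1L)) {
    res <- stats::integrate(f, pts[i], pts[i + 1L],
                            rel.tol = q$rel_tol, abs.tol = q$abs_tol,
                            subdivisions = q$max_subdivisions,
                            stop.on.error = FALSE)
    if (!res$message %in% c("OK", "roundoff error was detected")) {
      stop(sprintf("oracle error: quadrature did not converge on [%g, %g]: %s",
                   pts[i], pts[i + 1L], res$message), call. = FALSE)
    }
    total <- total + res$value
    err <- err + res$abs.error
  }
  structure(total, abs_error = err)
}

#' Reference potential by adaptive quadrature
#'
#' Independent numerical evaluation of the defining integral
#' `W = lambda Int_0^L U_SP(sqrt(y^2 + h^2)) dy` (in the shifted axial
#' coordinate), used to validate every closed-form branch.  Infinite rods
#' are truncated at `+/- truncation_length`.
#'
#' @inheritParams finite_rod_potential
#' @param q A [quadrature_spec()].
#' @return The potential (energy) with the accumulated absolute error
#'   estimate as attribute `"abs_error"`.
#' @export
quadrature_potential <- function(config, s, r, p = lj_params(),
                                 q = quadrature_spec()) {
  stopifnot(inherits(config, "local_config"), inherits(s, "lj_sphere"),
            inherits(r, "lj_rod"), inherits(p, "lj_params"),
            inherits(q, "quadrature_spec"))
  mind <- min_distance_to_rod(config, r)
  if (!(mind > s$a)) overlap_error(mind, s$a)
  h <- config$h
  f <- function(y) r$lambda * sphere_point_potential(sqrt(y^2 + h^2), s, p)
  if (is.infinite(r$L)) {
    lo <- -q$truncation_length * p$sigma
    hi <- q$truncation_length * p$sigma
  } else {
    y <- rod_endpoints_y(config, r)
    lo <- y[["y0"]]
    hi <- y[["yL"]]
  }
  # Split at the closest approach and a few widths around it.
  wall <- sqrt(max(mind^2 - h^2, 0)) # axial location of min distance, ~0
  splits <- c(0, -p$sigma, p$sigma, -10 * p$sigma, 10 * p$sigma, wall, -wall)
  out <- integrate_panels(f, lo, hi, splits, q)
  out
}

#' Reference torque by adaptive quadrature
#'
#' Torque on the rod about the reference point, computed by integrating
#' the lever-arm-weighted radial force density along the rod:
#' `tau_z = lambda * h * Int_0^L (x - l) U_SP'(r(x)) / r(x) dx`, with
#' `r(x) = sqrt(x^2 + rho^2 - 2 x rho cos(theta))` and `l = L/2`
#' (`rod_center`) or `l = 0` (`rod_end_O`).
#'
#' @inheritParams quadrature_potential
#' @param reference_point `"rod_center"` or `"rod_end_O"`.
#' @return Signed `n_z` torque component (energy units).
#' @export
quadrature_torque <- function(config, s, r, p = lj_params(),
                              q = quadrature_spec(),
                              reference_point = c("rod_center", "rod_end_O")) {
  reference_point <- match.arg(reference_point)
  if (is.infinite(r$L)) {
    stop("quadrature_torque(): finite rod required", call. = FALSE)
  }
  mind <- min_distance_to_rod(config, r)
  if (!(mind > s$a)) overlap_error(mind, s$a)
  l <- if (reference_point == "rod_center") r$L / 2 else 0
  rho <- config$rho
  cth <- cos(config$theta)
  f <- function(x) {
    rr <- sqrt(x^2 + rho^2 - 2 * x * rho * cth)
    (x - l) * sphere_point_potential_deriv(rr, s, p) / rr
  }
  splits <- config$x_c + c(0, -p$sigma, p$sigma)
  as.numeric(r$lambda * config$h *
               integrate_panels(f, 0, r$L, splits, q))
}

#' Sphere-point potential by volume quadrature
#'
#' Independent check of the closed-form sphere-point potential: 2-D
#' quadrature (shell radius x polar angle) of the LJ 12-6 pair potential
#' over the sphere volume at density `rho_s`.
#'
#' @param r_point Distance from the sphere center to the point particle;
#'   must exceed the sphere radius.
#' @inheritParams quadrature_potential
#' @return Energy.
#' @export
sphere_volume_quadrature <- function(r_point, s, p = lj_params(),
                                     q = quadrature_spec()) {
  stopifnot(inherits(s, "lj_sphere"), inherits(p, "lj_params"))
  if (!(r_point > s$a)) overlap_error(r_point, s$a)
  shell <- function(t) {
    # integral over the polar angle of one shell of radius t
    vapply(t, function(tt) {
      g <- function(phi) {
        d <- sqrt(r_point^2 + tt^2 - 2 * r_point * tt * cos(phi))
        lj_pair(d, p) * sin(phi)
      }
      res <- stats::integrate(g, 0, pi, rel.tol = q$rel_tol,
                              subdivisions = q$max_subdivisions)
      2 * pi * tt^2 * res$value
    }, numeric(1))
  }
  res <- stats::integrate(shell, 0, s$a, rel.tol = q$rel_tol,
                          subdivisions = q$max_subdivisions)
  s$rho_s * res$value
}
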