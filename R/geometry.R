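#' Local sphere-rod configuration
#'
#' The canonical local frame: the x-axis runs along the rod's central axis
#' with the origin at the rod end O, and the sphere center sits at polar
#' coordinates (`rho`, `theta`) with `theta` measured from the rod
#' direction, always in `[0, pi]`.  Derived quantities are the
#' perpendicular distance from the sphere center to the rod axis,
#' `h = rho * sin(theta)`, and the axial coordinate of the center's
#' projection, `x_c = rho * cos(theta)`.  For a rod of length `L` the rod
#' endpoints in the axis coordinate shifted to that projection are
#' `y0 = -x_c` and `yL = L - x_c`.
#'
#' @param rho Distance from the rod end O (the origin) to the sphere
#'   center; >= 0.
#' @param theta Polar angle in `[0, pi]` between the rod direction (O to L)
#'   and the direction from O to the sphere center.
#'
#' @return An object of class `local_config` with fields `rho`, `theta`,
#'   `h`, `x_c`.
#' @examples
#' local_config(rho = 12, theta = pi / 6)
#' @export
local_config <- function(rho, theta) {
  stopifnot(
    is.numeric(rho), length(rho) == 1L, is.finite(rho), rho >= 0,
    is.numeric(theta), length(theta) == 1L, is.finite(theta),
    theta >= 0, theta <= pi
  )
  rho <- as.numeric(rho)
  theta <- as.numeric(theta)
  structure(
    list(rho = rho, theta = theta,
         h = rho * sin(theta), x_c = rho * cos(theta)),
    class = "local_config"
  )
}

#' @export
print.local_config <- function(x, ...) {
  cat(sprintf("<local_config> rho = %g, theta = %g (h = %g, x_c = %g)\n",
              x$rho, x$theta, x$h, x$x_c))
  invisible(x)
}

#' Global sphere-rod configuration
#'
#' Cartesian coordinates of the sphere center and of the two rod ends in
#' an arbitrary (global) frame.  Only finite rods are representable in
#' global form.
#'
#' @param sphere_center,rod_end_O,rod_end_L Numeric 3-vectors.
#' @return An object of class `global_config`.
#' @examples
#' global_config(c(0, 5, 0), c(0, 0, 0), c(4, 0, 0))
#' @export
global_config <- function(sphere_center, rod_end_O, rod_end_L) {
  as_vec3 <- function(v, what) {
    if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v))) {
      stop(sprintf("global_config(): %s must be a finite numeric 3-vector", what),
           call. = FALSE)
    }
    as.numeric(v)
  }
  structure(
    list(sphere_center = as_vec3(sphere_center, "sphere_center"),
         rod_end_O = as_vec3(rod_end_O, "rod_end_O"),
         rod_end_L = as_vec3(rod_end_L, "rod_end_L")),
    class = "global_config"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(v) sqrt(sum(v * v))

# Deterministic unit vector perpendicular to unit vector n: zero out the
# smallest-magnitude component, swap and negate the other two.
perp_unit <- function(n) {
  k <- which.min(abs(n))
  e <- c(0, 0, 0)
  e[k] <- 1
  v <- cross3(n, e)
  v / norm3(v)
}

#' Convert a global configuration to the local frame
#'
#' Builds the local polar coordinates and the orthonormal-ish frame basis
#' from Cartesian coordinates.  The basis holds the unit vectors `n_x`
#' (along the rod, O to L), `n_rho` (from O to the sphere center), `n_z`
#' (`(n_x x n_rho)/sin(theta)`, the torque axis) and the convenience unit
#' vector `n_h` perpendicular to the rod axis pointing from the axis to
#' the sphere center.  When the sphere center lies on the rod axis
#' (`sin(theta) = 0`) the perpendicular pair (`n_z`, `n_h`) is chosen
#' deterministically from the smallest-magnitude component of `n_x` so
#' that global wrench output is reproducible.
#'
#' @param g A [global_config()].
#' @return A list with components `config` (a [local_config()]), `basis`
#'   (list of unit 3-vectors `n_x`, `n_rho`, `n_z`, `n_h`) and `L` (the
#'   rod length implied by the endpoints).
#' @examples
#' local_config_from_global(global_config(c(0, 5, 0), c(0, 0, 0), c(4, 0, 0)))
#' @export
local_config_from_global <- function(g) {
  stopifnot(inherits(g, "global_config"))
  axis <- g$rod_end_L - g$rod_end_O
  L <- norm3(axis)
  if (L <= 0 || !is.finite(L)) {
    stop("invalid geometry: rod endpoints coincide", call. = FALSE)
  }
  n_x <- axis / L
  d <- g$sphere_center - g$rod_end_O
  rho <- norm3(d)
  if (rho > 0) {
    n_rho <- d / rho
    cth <- sum(n_x * n_rho)
    cth <- min(1, max(-1, cth))
    cr <- cross3(n_x, n_rho)
    sth <- norm3(cr)
    theta <- atan2(sth, cth)
    if (sth > 1e-14) {
      n_z <- cr / sth
      n_h <- cross3(n_z, n_x)
    } else {
      n_z <- perp_unit(n_x)
      n_h <- cross3(n_z, n_x)
      theta <- if (cth >= 0) 0 else pi
    }
  } else {
    # Sphere center at rod end O: theta is arbitrary; pick 0.
    n_rho <- n_x
    theta <- 0
    n_z <- perp_unit(n_x)
    n_h <- cross3(n_z, n_x)
  }
  list(config = local_config(rho, min(pi, max(0, theta))),
       basis = list(n_x = n_x, n_rho = n_rho, n_z = n_z, n_h = n_h),
       L = L)
}

# Rod endpoint coordinates in the axial coordinate centered on the sphere
# projection: y0 = -x_c, yL = L - x_c.
rod_endpoints_y <- function(config, r) {
  stopifnot(inherits(config, "local_config"), inherits(r, "lj_rod"))
  c(y0 = -config$x_c, yL = r$L - config$x_c)
}

#' Minimum distance from the sphere center to the rod segment
#'
#' Supports the validity condition of the integrated potential: the closed
#' forms are finite as long as the rod (the segment, not its infinite
#' axis) stays outside the sphere.
#'
#' @param config A [local_config()].
#' @param r An [rod()]; may be infinite.
#' @return The minimum distance from the sphere center to any point of the
#'   rod segment.
#' @examples
#' min_distance_to_rod(local_config(5, pi / 2), rod(4))  # 5
#' min_distance_to_rod(local_config(5, 0), rod(4))       # 1
#' @export
min_distance_to_rod <- function(config, r) {
  y <- rod_endpoints_y(config, r)
  h <- config$h
  if (y[["y0"]] <= 0 && 0 <= y[["yL"]]) {
    h
  } else {
    ymin <- min(abs(y[is.finite(y)]))
    sqrt(h^2 + ymin^2)
  }
}

#' Test that a configuration is overlap-free
#'
#' `TRUE` iff the rod segment lies strictly outside the sphere
#' (`min_distance_to_rod > a`).  The test is strict with no tolerance;
#' callers wanting a safety margin should pass an inflated radius.
#'
#' @param config A [local_config()].
#' @param s A [sphere()].
#' @param r An [rod()].
#' @return Logical scalar.
#' @export
validate_no_overlap <- function(config, s, r) {
  stopifnot(inherits(s, "lj_sphere"))
  min_distance_to_rod(config, r) > s$a
}

#' Perpendicular-bisector configuration
#'
#' Places the sphere center on the perpendicular bisector of a rod of
#' length `L` at distance `h` from its axis: `x_c = L/2`, so
#' `rho = sqrt(h^2 + L^2/4)` and `theta = atan2(h, L/2)`.  This is the
#' configuration that maximizes the sphere-rod attraction by symmetry and
#' the one used throughout the adhesion analysis.
#'
#' @param L Rod length (> 0, finite).
#' @param h Perpendicular distance from the sphere center to the rod axis
#'   (> 0).
#' @return A [local_config()].
#' @examples
#' bisector_config(L = 2, h = 1)  # theta = pi/4, rho = sqrt(2)
#' @export
bisector_config <- function(L, h) {
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L), L > 0,
            is.numeric(h), length(h) == 1L, is.finite(h), h > 0)
  local_config(rho = sqrt(h^2 + L^2 / 4), theta = atan2(h, L / 2))
}

overlap_error <- function(min_dist, a) {
  stop(structure(
    class = c("rodsphere_overlap_error", "error", "condition"),
    list(message = sprintf(
           "overlapping configuration: min rod-center distance %.6g <= sphere radius %.6g",
           min_dist, a),
         call = NULL, min_distance = min_dist, a = a)
  ))
}
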