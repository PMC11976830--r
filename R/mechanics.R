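#' Force-torque pair (wrench)
#'
#' Container for a force and a torque about a stated reference point,
#' either in the local rod frame (components along `n_x`, `n_h`, `n_z`:
#' rod axis, in-plane perpendicular towards the sphere center, torque
#' axis) or in the global Cartesian frame.
#'
#' @param force,torque Numeric 3-vectors.
#' @param reference_point One of `"sphere_center"`, `"rod_center"`,
#'   `"rod_end_O"`.
#' @param frame `"local"` or `"global"`.
#' @return An object of class `rodsphere_wrench`.
#' @export
wrench <- function(force = c(0, 0, 0), torque = c(0, 0, 0),
                   reference_point = "rod_center", frame = "local") {
  stopifnot(is.numeric(force), length(force) == 3L,
            is.numeric(torque), length(torque) == 3L)
  structure(list(force = as.numeric(force), torque = as.numeric(torque),
                 reference_point = reference_point, frame = frame),
            class = "rodsphere_wrench")
}

#' @export
print.rodsphere_wrench <- function(x, ...) {
  cat(sprintf("<wrench %s frame, ref %s>\n  force  = (%.6g, %.6g, %.6g)\n  torque = (%.6g, %.6g, %.6g)\n",
              x$frame, x$reference_point,
              x$force[1], x$force[2], x$force[3],
              x$torque[1], x$torque[2], x$torque[3]))
  invisible(x)
}

#' @method as_tibble rodsphere_wrench
#' @export
as_tibble.rodsphere_wrench <- function(x, ...) {
  tibble::tibble(Fx = x$force[1], Fy = x$force[2], Fz = x$force[3],
                 Tx = x$torque[1], Ty = x$torque[2], Tz = x$torque[3],
                 ref_point = x$reference_point, frame = x$frame)
}

# Richardson-extrapolated central differences (two levels, three step
# sizes), O(step^6) truncation.
richardson_fd <- function(f, x, step) {
  d <- vapply(c(step, step / 2, step / 4),
              function(s) (f(x + s) - f(x - s)) / (2 * s), numeric(1))
  d12 <- (4 * d[2] - d[1]) / 3
  d23 <- (4 * d[3] - d[2]) / 3
  (16 * d23 - d12) / 15
}

#' Partial derivatives of the integrated potential
#'
#' Computes the four partials of `W` with respect to the local coordinates
#' of the sphere center: the polar pair (`rho`, `theta`) and the Cartesian
#' pair (`x_c`, `h`).  `dW/dx_c` follows exactly from the antiderivative
#' property (an axial shift of the sphere only moves the rod endpoints in
#' the shifted coordinate):
#' `dW/dx_c = lambda * (U_SP(r(y0)) - U_SP(r(yL)))`.  `dW/dh` uses the
#' closed-form derivative for infinite rods and Richardson-extrapolated
#' central differences of the analytic potential for finite rods (accuracy
#' ~1e-6 relative or better).  The polar partials follow from the chain
#' rule `dW/drho = cos(theta) dW/dx_c + sin(theta) dW/dh`,
#' `dW/dtheta = rho (-sin(theta) dW/dx_c + cos(theta) dW/dh)`.
#'
#' @inheritParams finite_rod_potential
#' @return A list of class `potential_partials` with `dW_drho`,
#'   `dW_dtheta`, `dW_dh`, `dW_dxc`.
#' @export
potential_partials <- function(config, s, r, p = lj_params()) {
  stopifnot(inherits(config, "local_config"), inherits(s, "lj_sphere"),
            inherits(r, "lj_rod"), inherits(p, "lj_params"))
  h <- config$h
  x_c <- config$x_c
  if (is.infinite(r$L)) {
    if (!(h > s$a)) overlap_error(h, s$a)
    dW_dh <- infinite_rod_dWdh(h, s, r$lambda, p)
    dW_dxc <- 0
  } else {
    mind <- min_distance_to_rod(config, r)
    if (!(mind > s$a)) overlap_error(mind, s$a)
    y <- rod_endpoints_y(config, r)
    r0 <- sqrt(y[["y0"]]^2 + h^2)
    rL <- sqrt(y[["yL"]]^2 + h^2)
    dW_dxc <- r$lambda * (sphere_point_potential(r0, s, p) -
                            sphere_point_potential(rL, s, p))
    clearance <- mind - s$a
    step <- min(1e-3 * p$sigma, clearance / 8)
    f <- function(hh) {
      finite_rod_potential(config_from_xc_h(x_c, abs(hh)), s, r, p)$W
    }
    dW_dh <- richardson_fd(f, h, step)
  }
  th <- config$theta
  structure(
    list(
      dW_drho = cos(th) * dW_dxc + sin(th) * dW_dh,
      dW_dtheta = config$rho * (-sin(th) * dW_dxc + cos(th) * dW_dh),
      dW_dh = dW_dh,
      dW_dxc = dW_dxc
    ),
    class = "potential_partials"
  )
}

#' Force on the sphere
#'
#' The force on the sphere is minus the gradient of `W` with respect to
#' the sphere-center position.  The polar form
#' `F_S = (1/(rho sin theta)) dW/dtheta n_x - (dW/drho +
#' (cos theta/(rho sin theta)) dW/dtheta) n_rho` has a removable
#' singularity at `sin(theta) = 0`; the implementation therefore uses the
#' equivalent Cartesian parametrization
#' `F_S = -dW/dx_c n_x - dW/dh n_h`, which is finite for collinear
#' configurations.  Local-frame components are along `(n_x, n_h, n_z)`.
#'
#' @inheritParams finite_rod_potential
#' @return A `rodsphere_wrench` (force only; the torque on the sphere
#'   about its own center vanishes by the spherical symmetry of the
#'   continuum body under central pair forces).
#' @export
force_on_sphere <- function(config, s, r, p = lj_params()) {
  pp <- potential_partials(config, s, r, p)
  wrench(force = c(-pp$dW_dxc, -pp$dW_dh, 0),
         reference_point = "sphere_center", frame = "local")
}

#' Force on the rod
#'
#' Exact negation of [force_on_sphere()] (Newton's third law).
#'
#' @inheritParams finite_rod_potential
#' @return A `rodsphere_wrench`.
#' @export
force_on_rod <- function(config, s, r, p = lj_params()) {
  fs <- force_on_sphere(config, s, r, p)
  wrench(force = -fs$force, reference_point = "rod_center", frame = "local")
}

#' Torque on the rod
#'
#' Analytical torque exerted by the sphere on a finite rod, along the
#' local `n_z` axis.  About the rod center:
#' \deqn{\tau_z = -\frac{L}{2}\sin\theta\,\frac{\partial W}{\partial\rho}
#'   + \left(1 - \frac{L}{2\rho}\cos\theta\right)
#'     \frac{\partial W}{\partial\theta}}
#' About the rod end O it reduces to `dW/dtheta`.  The torque vanishes for
#' collinear configurations (`theta = 0` or `pi`) and, for the
#' center-referenced case, whenever the sphere center lies on the
#' perpendicular bisector of the rod (`rho = L / (2 cos theta)`).
#' Infinite rods are rejected: the expression presumes a finite `L`.
#'
#' @inheritParams finite_rod_potential
#' @param reference_point `"rod_center"` or `"rod_end_O"`.
#' @return A `rodsphere_wrench` (torque only).
#' @export
torque_on_rod <- function(config, s, r, p = lj_params(),
                          reference_point = c("rod_center", "rod_end_O")) {
  reference_point <- match.arg(reference_point)
  if (is.infinite(r$L)) {
    stop("torque_on_rod(): unsupported for infinite rods (finite L required)",
         call. = FALSE)
  }
  pp <- potential_partials(config, s, r, p)
  tau_z <- if (reference_point == "rod_end_O") {
    pp$dW_dtheta
  } else {
    th <- config$theta
    -(r$L / 2) * sin(th) * pp$dW_drho +
      (1 - (r$L / (2 * config$rho)) * cos(th)) * pp$dW_dtheta
  }
  wrench(torque = c(0, 0, tau_z), reference_point = reference_point,
         frame = "local")
}

#' Global-frame wrenches on sphere and rod
#'
#' Computes the local-frame force and torque and rotates them into the
#' global frame through the unit vectors of the configuration basis
#' (`n_x`, `n_h`, `n_z`).
#'
#' @param g A [global_config()].
#' @param s A [sphere()].
#' @param r An [rod()]; its length must match the rod endpoints in `g`.
#' @param p An [lj_params()].
#' @param reference_point Reference point for the rod torque.
#' @return A list with `sphere` and `rod` wrenches (class
#'   `rodsphere_wrench`, frame `"global"`), plus the `local` conversion
#'   (config and basis) as attribute `"local"`.
#' @export
wrench_global <- function(g, s, r, p = lj_params(),
                          reference_point = c("rod_center", "rod_end_O")) {
  reference_point <- match.arg(reference_point)
  loc <- local_config_from_global(g)
  if (is.finite(r$L) && abs(loc$L - r$L) > 1e-9 * max(1, r$L)) {
    stop("wrench_global(): rod length does not match the global endpoints",
         call. = FALSE)
  }
  pp <- potential_partials(loc$config, s, r, p)
  tau_z <- if (reference_point == "rod_end_O") {
    pp$dW_dtheta
  } else {
    th <- loc$config$theta
    -(r$L / 2) * sin(th) * pp$dW_drho +
      (1 - (r$L / (2 * loc$config$rho)) * cos(th)) * pp$dW_dtheta
  }
  b <- loc$basis
  f_sphere <- -pp$dW_dxc * b$n_x - pp$dW_dh * b$n_h
  list(
    sphere = wrench(force = f_sphere, torque = c(0, 0, 0),
                    reference_point = "sphere_center", frame = "global"),
    rod = wrench(force = -f_sphere, torque = tau_z * b$n_z,
                 reference_point = reference_point, frame = "global")
  )
}
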