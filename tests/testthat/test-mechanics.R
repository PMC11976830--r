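p0 <- lj_params()

fd_partial <- function(f, x, step = 1e-5) {
  rodsphere:::richardson_fd(f, x, step)
}

test_that("potential partials match finite differences of the potential", {
  set.seed(101)
  for (i in 1:25) {
    cs <- rand_case_nonzero(sample(c("above", "below"), 1))
    pp <- potential_partials(cs$cfg, cs$s, cs$r, p0)
    Wfun_rho <- function(rho) {
      finite_rod_potential(local_config(rho, cs$cfg$theta), cs$s, cs$r, p0)$W
    }
    Wfun_theta <- function(th) {
      finite_rod_potential(local_config(cs$cfg$rho, th), cs$s, cs$r, p0)$W
    }
    Wfun_xc <- function(xc) {
      finite_rod_potential(config_from_xc_h(xc, cs$cfg$h), cs$s, cs$r, p0)$W
    }
    scale <- max(abs(pp$dW_drho), abs(pp$dW_dtheta), abs(pp$dW_dxc), 1e-10)
    expect_lt(abs(pp$dW_drho - fd_partial(Wfun_rho, cs$cfg$rho)) / scale, 1e-6)
    th <- cs$cfg$theta
    step_th <- min(1e-5, (pi - th) / 4, th / 4)
    if (step_th > 1e-9) {
      expect_lt(abs(pp$dW_dtheta - fd_partial(Wfun_theta, th, step_th)) /
                  scale, 1e-5)
    }
    expect_lt(abs(pp$dW_dxc - fd_partial(Wfun_xc, cs$cfg$x_c)) / scale, 1e-6)
    # chain-rule identities
    expect_equal(pp$dW_drho,
                 cos(th) * pp$dW_dxc + sin(th) * pp$dW_dh, tolerance = 1e-12)
    expect_equal(pp$dW_dtheta,
                 cs$cfg$rho * (-sin(th) * pp$dW_dxc + cos(th) * pp$dW_dh),
                 tolerance = 1e-12)
  }
})

test_that("dW/dx_c vanishes over the rod midpoint by symmetry", {
  cfg <- bisector_config(6, 4)
  pp <- potential_partials(cfg, sphere(3), rod(6), p0)
  expect_equal(pp$dW_dxc, 0, tolerance = 1e-14)
})

test_that("infinite-rod dW/dh uses the closed form", {
  s <- sphere(10)
  cfg <- local_config(13, pi / 2)
  pp <- potential_partials(cfg, s, rod(Inf), p0)
  expect_equal(pp$dW_dh, rodsphere:::infinite_rod_dWdh(13, s, 1, p0))
  # cross-check against finite differences of the closed-form potential
  fd <- fd_partial(function(h) infinite_rod_potential(h, s, 1, p0)$W, 13)
  expect_equal(pp$dW_dh, fd, tolerance = 1e-9)
})

test_that("force on the sphere is minus the spatial gradient of W", {
  set.seed(202)
  for (i in 1:15) {
    cs <- rand_case_nonzero(sample(c("above", "below"), 1))
    fs <- force_on_sphere(cs$cfg, cs$s, cs$r, p0)
    gx <- fd_partial(function(xc)
      finite_rod_potential(config_from_xc_h(xc, cs$cfg$h), cs$s, cs$r, p0)$W,
      cs$cfg$x_c)
    gh <- fd_partial(function(h)
      finite_rod_potential(config_from_xc_h(cs$cfg$x_c, abs(h)), cs$s,
                           cs$r, p0)$W,
      cs$cfg$h, min(1e-5, (min_distance_to_rod(cs$cfg, cs$r) - cs$s$a) / 8))
    scale <- max(abs(gx), abs(gh), 1e-10)
    expect_lt(abs(fs$force[1] + gx) / scale, 1e-6)
    expect_lt(abs(fs$force[2] + gh) / scale, 1e-6)
    expect_identical(fs$force[3], 0)
  }
})

test_that("collinear configurations give a purely axial force", {
  cfg <- local_config(12, 0)      # sphere ahead of the far rod end
  fs <- force_on_sphere(cfg, sphere(3), rod(5), p0)
  expect_equal(fs$force[2], 0, tolerance = 1e-12)
  expect_false(fs$force[1] == 0)
})

test_that("bisector configurations give a purely perpendicular force", {
  cfg <- bisector_config(8, 5)
  fs <- force_on_sphere(cfg, sphere(4), rod(8), p0)
  expect_equal(fs$force[1], 0, tolerance = 1e-12)
  expect_false(fs$force[2] == 0)
})

test_that("Newton's third law holds exactly for the rod force", {
  cs <- rand_case_nonzero("above")
  fs <- force_on_sphere(cs$cfg, cs$s, cs$r, p0)
  fr <- force_on_rod(cs$cfg, cs$s, cs$r, p0)
  expect_identical(fr$force, -fs$force)
})

test_that("rod force equals the quadrature of the segment-force density", {
  # integrate the axial and radial force densities along the rod
  set.seed(303)
  for (i in 1:8) {
    cs <- rand_case_nonzero("above")
    rho <- cs$cfg$rho; th <- cs$cfg$theta
    fr <- force_on_rod(cs$cfg, cs$s, cs$r, p0)
    # force density on a segment at x points from the segment toward the
    # sphere center: dF = -lambda U'(r) (x_vec - c_vec)/r, in local
    # Cartesian coordinates (axis along x, center at (x_c, h)).
    fx_dens <- function(x) {
      r <- sqrt(x^2 + rho^2 - 2 * x * rho * cos(th))
      -cs$r$lambda *
        rodsphere:::sphere_point_potential_deriv(r, cs$s, p0) *
        (x - cs$cfg$x_c) / r
    }
    fh_dens <- function(x) {
      r <- sqrt(x^2 + rho^2 - 2 * x * rho * cos(th))
      -cs$r$lambda *
        rodsphere:::sphere_point_potential_deriv(r, cs$s, p0) *
        (0 - cs$cfg$h) / r
    }
    Fx <- integrate(fx_dens, 0, cs$r$L, rel.tol = 1e-12)$value
    Fh <- integrate(fh_dens, 0, cs$r$L, rel.tol = 1e-12)$value
    scale <- max(abs(Fx), abs(Fh))
    expect_lt(abs(fr$force[1] - Fx) / scale, 1e-7)
    expect_lt(abs(fr$force[2] - Fh) / scale, 1e-7)
  }
})

test_that("the segment potential identity relating rho and theta derivatives holds", {
  # x (dw/drho + cot(theta)/rho * x-free dw/dtheta) = (1/sin) dw/dtheta for
  # w depending on x, rho, theta only through r.
  set.seed(404)
  s <- sphere(2)
  for (i in 1:15) {
    x <- runif(1, -5, 5)
    rho <- runif(1, 3, 9)
    th <- runif(1, 0.2, pi - 0.2)
    w <- function(rho_, th_) {
      r <- sqrt(x^2 + rho_^2 - 2 * x * rho_ * cos(th_))
      sphere_point_potential(r, s, p0)
    }
    r0 <- sqrt(x^2 + rho^2 - 2 * x * rho * cos(th))
    if (r0 < s$a + 0.3) next
    dw_drho <- fd_partial(function(rr) w(rr, th), rho)
    dw_dth <- fd_partial(function(tt) w(rho, tt), th)
    lhs <- x * (dw_drho + cos(th) / (rho * sin(th)) * dw_dth)
    rhs <- dw_dth / sin(th)
    expect_equal(lhs, rhs, tolerance = 1e-5 * max(abs(rhs), 1e-8))
  }
})

test_that("torque about the rod center matches the lever-arm quadrature", {
  set.seed(505)
  q <- quadrature_spec(rel_tol = 1e-12)
  for (i in 1:30) {
    cs <- rand_case_nonzero(sample(c("above", "below"), 1))
    for (ref in c("rod_center", "rod_end_O")) {
      tq <- torque_on_rod(cs$cfg, cs$s, cs$r, p0, ref)
      tq_or <- quadrature_torque(cs$cfg, cs$s, cs$r, p0, q, ref)
      scale <- max(abs(tq_or),
                   abs(finite_rod_potential(cs$cfg, cs$s, cs$r, p0)$W))
      expect_lt(abs(tq$torque[3] - tq_or) / scale, 1e-6)
    }
  }
})

test_that("torque vanishes for collinear and bisector configurations", {
  s <- sphere(3)
  r <- rod(5)
  for (th in c(0, pi)) {
    cfg <- local_config(12, th)
    expect_equal(torque_on_rod(cfg, s, r, p0, "rod_center")$torque[3], 0,
                 tolerance = 1e-12)
    expect_equal(torque_on_rod(cfg, s, r, p0, "rod_end_O")$torque[3], 0,
                 tolerance = 1e-12)
  }
  # perpendicular bisector: rho = L / (2 cos(theta))
  cfg <- bisector_config(5, 4)
  expect_equal(torque_on_rod(cfg, s, r, p0, "rod_center")$torque[3], 0,
               tolerance = 1e-10)
  expect_error(torque_on_rod(local_config(5, pi / 2), s, rod(Inf), p0),
               "infinite")
})

test_that("global wrenches are rotation-equivariant and translation-invariant", {
  set.seed(606)
  cs <- rand_case_nonzero("above")
  L <- cs$r$L
  base_O <- c(0, 0, 0)
  base_E <- c(L, 0, 0)
  ctr <- c(cs$cfg$x_c, cs$cfg$h, 0)
  g0 <- global_config(ctr, base_O, base_E)
  w0 <- wrench_global(g0, cs$s, cs$r, p0)
  # random rotation (QR of a random matrix) and translation
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tvec <- rnorm(3, sd = 10)
  g1 <- global_config(as.numeric(R %*% ctr + tvec),
                      as.numeric(R %*% base_O + tvec),
                      as.numeric(R %*% base_E + tvec))
  w1 <- wrench_global(g1, cs$s, cs$r, p0)
  # the finite-difference dW/dh limits the reproducibility of re-derived
  # local coordinates to the partials' own 1e-6 relative contract
  fscale <- sqrt(sum(w0$sphere$force^2))
  tscale <- max(sqrt(sum(w0$rod$torque^2)), fscale)
  expect_lt(max(abs(w1$sphere$force - as.numeric(R %*% w0$sphere$force))) /
              fscale, 1e-6)
  expect_lt(max(abs(w1$rod$torque - as.numeric(R %*% w0$rod$torque))) /
              tscale, 1e-6)
  # pure translation leaves the wrench unchanged
  g2 <- global_config(ctr + 5, base_O + 5, base_E + 5)
  w2 <- wrench_global(g2, cs$s, cs$r, p0)
  expect_lt(max(abs(w2$sphere$force - w0$sphere$force)) / fscale, 1e-6)
  expect_lt(max(abs(w2$rod$torque - w0$rod$torque)) / tscale, 1e-6)
})

test_that("work along a small displacement equals the potential drop", {
  cs <- rand_case_nonzero("above")
  L <- cs$r$L
  g0 <- global_config(c(cs$cfg$x_c, cs$cfg$h, 0), c(0, 0, 0), c(L, 0, 0))
  w0 <- wrench_global(g0, cs$s, cs$r, p0)
  d <- 1e-6 * c(0.3, -0.5, 0.8)
  g1 <- global_config(c(cs$cfg$x_c, cs$cfg$h, 0) + d, c(0, 0, 0), c(L, 0, 0))
  W0 <- finite_rod_potential(cs$cfg, cs$s, cs$r, p0)$W
  cfg1 <- local_config_from_global(g1)$config
  W1 <- finite_rod_potential(cfg1, cs$s, cs$r, p0)$W
  work <- sum(w0$sphere$force * d)
  expect_lt(abs(work + (W1 - W0)) / max(abs(W1 - W0), 1e-12), 1e-3)
})

test_that("force magnitude decays monotonically beyond the well on the bisector", {
  s <- sphere(5)
  r <- rod(20)
  h0 <- find_h0(s, r, p0)$h0
  hs <- seq(h0 + 1, h0 + 5, length.out = 9)
  fmag <- vapply(hs, function(h) {
    sqrt(sum(force_on_sphere(bisector_config(20, h), s, r, p0)$force^2))
  }, numeric(1))
  expect_true(all(diff(fmag) < 0))
})
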