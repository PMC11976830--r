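# Shared fixtures: deterministic random configuration generators spanning
# the three closed-form branches, and a relative-error helper.

rel_err <- function(x, ref) {
  abs(x - ref) / max(abs(ref), .Machine$double.xmin)
}

# One random non-overlapping configuration.  `branch` picks the geometry
# family; "near" places |h - a| inside the near-tangency cancellation band.
# Configurations with |W| below `w_floor` (razor-thin zero crossings, where
# a relative comparison is numerically meaningless) are rejected upstream.
rand_case <- function(branch = c("above", "below", "near")) {
  branch <- match.arg(branch)
  a <- runif(1, 2, 12)
  L <- runif(1, 0.5, 25)
  s <- sphere(a, rho_s = runif(1, 0.5, 2))
  r <- rod(L, lambda = runif(1, 0.5, 2))
  if (branch == "above") {
    h <- a + runif(1, 0.05, 4)
    x_c <- runif(1, -L, 2 * L)       # any axial placement is valid
  } else if (branch == "below") {
    h <- runif(1, 0.1, 0.95) * a
    gap <- runif(1, 0.05, 4)
    ymin <- sqrt(a^2 - h^2) + gap    # keep the whole segment outside
    x_c <- if (runif(1) < 0.5) -ymin else L + ymin
  } else {
    h <- a + sample(c(-1, 1), 1) * 10^runif(1, -5.5, -2.1)
    gap <- runif(1, 0.05, 2)
    ymin <- sqrt(max(a^2 - h^2, 0)) + gap
    x_c <- if (runif(1) < 0.5) -ymin else L + ymin
  }
  cfg <- config_from_xc_h(x_c, h)
  list(cfg = cfg, s = s, r = r)
}

# Rejection-sampled case whose potential is not at a razor-thin zero
# crossing, so that relative comparisons against the oracle are meaningful.
rand_case_nonzero <- function(branch, p = lj_params(), w_floor = 1e-8) {
  for (i in 1:100) {
    cs <- rand_case(branch)
    if (!validate_no_overlap(cs$cfg, cs$s, cs$r)) next
    W <- finite_rod_potential(cs$cfg, cs$s, cs$r, p)$W
    if (is.finite(W) && abs(W) > w_floor) return(cs)
  }
  stop("helper: failed to draw a usable configuration")
}

# internal helpers reached through the namespace in tests
config_from_xc_h <- rodsphere:::config_from_xc_h
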