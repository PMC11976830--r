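---
title: "Integrated sphere-rod Lennard-Jones interactions: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated sphere-rod Lennard-Jones interactions: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodsphere)
```

## The model

`rodsphere` computes the Hamaker-integrated Lennard-Jones 12-6
interaction between two continuum bodies: a solid sphere of radius $a$
uniformly filled with LJ material points at number density $\rho_s$, and
a thin rod — a one-dimensional material line of length $L$ with line
density $\lambda$ and no cross-sectional radius.  Every pair of material
points interacts through
$$U(r) = 4\epsilon\left[(\sigma/r)^{12} - (\sigma/r)^6\right],$$
and the body-body potential is the pairwise integral of $U$ over both
bodies.  Integrating over the sphere gives the closed sphere-point
potential $U_{SP}(r)$ (valid for $r > a$); integrating $U_{SP}$ along the
rod gives the sphere-rod potential.

In the rod's local frame (origin at rod end O, $x$ along the axis, the
sphere center at polar coordinates $(\rho, \theta)$ with
$0 \le \theta \le \pi$) the rod integral has a closed antiderivative
$G(y, h)$ in the shifted axial coordinate $y = x - \rho\cos\theta$, where
$h = \rho\sin\theta$ is the perpendicular axis-center distance:
$$W = \frac{2\lambda\rho_s a^3 \sigma^6 A_{cs}}{9}
      \left[G(y_L, h) - G(y_0, h)\right], \qquad A_{cs} = 24\pi\epsilon .$$

The primitive takes three algebraically different forms:

* **axis outside the sphere** ($h > a$): rational terms in
  $(h^2 - a^2)^{-k}$, $k = 1..8$, plus an arctangent term with
  $(h^2-a^2)^{-17/2}$;
* **axis piercing the sphere, rod outside it** ($h < a$): the same
  rational terms (now with $h^2 - a^2 < 0$) plus a real logarithm — the
  arctangent of an imaginary argument recombines across the two endpoints
  into a logarithm whose argument is positive for every non-overlapping
  rod;
* **tangent** ($h = a$): a separate closed form in pure powers of $y$
  (the $(h^2-a^2)^{-k}$ terms cancel in the endpoint difference, leaving
  their finite limit).

The potential is finite for every configuration in which the rod segment
(not its infinite axis) lies strictly outside the sphere; overlap is
detected with the exact point-segment distance and reported as a typed
error.  Infinite rods reduce to a one-variable potential $W(h)$, and the
limits are consistent: $L \to 0$ at fixed line mass recovers the
sphere-point potential, $a \to 0$ at fixed sphere mass recovers the
point-rod potential.

### Forces and torques

The force on the sphere is $-\nabla W$ with respect to the sphere-center
position.  The polar form contains a removable $1/(\rho\sin\theta)$
singularity, so all force paths use the Cartesian parametrization of the
center, $(x_c, h)$:
$$\mathbf{F}_S = -\frac{\partial W}{\partial x_c}\,\mathbf{n}_x
               - \frac{\partial W}{\partial h}\,\mathbf{n}_h,$$
which stays finite for collinear configurations ($\sin\theta = 0$, where
$\partial W/\partial h = 0$ by symmetry since $W$ is even in $h$).  The
axial partial is exact: shifting the sphere axially only moves the rod
endpoints in $y$, so $\partial W/\partial x_c = \lambda\,[U_{SP}(r(y_0)) -
U_{SP}(r(y_L))]$ by the antiderivative property.  The torque on a finite
rod about its center is
$$\tau_z = -\tfrac{L}{2}\sin\theta\,\partial_\rho W +
           \left(1 - \tfrac{L}{2\rho}\cos\theta\right)\partial_\theta W,$$
and about the O-end simply $\partial_\theta W$; both vanish for
collinear configurations, and the center-referenced torque also vanishes
with the sphere on the rod's perpendicular bisector.  The torque axis is
$\mathbf{n}_z = (\mathbf{n}_x \times \mathbf{n}_\rho)/\sin\theta$; for
on-axis centers the perpendicular pair is chosen deterministically from
the smallest-magnitude component of the rod direction so that global
wrench output is reproducible.  Torques for infinite rods are rejected
rather than returned as zero: the expression presumes a finite lever arm.
The torque on the *sphere* about its own center is returned as zero; for
a uniform sphere interacting through central pair forces every elementary
force points through the center.  (This is our inference from symmetry,
asserted as a property, not an external result.)

### Adhesion analysis

With the sphere center on the rod's perpendicular bisector (the
attraction-maximizing arrangement), the potential is a one-variable
function $W(L, h)$.  Its minimum $h_0$ defines the equilibrium gap
$\delta h = h_0 - a$ and the adhesion depth $\Delta W = |W(L, h_0)|$.
Stationarity gives closed conditions on $h_0$: for the sphere-point limit
$$\left(h_0 - a\right)^6 = \frac{2\,(5a^6 + 27a^4h_0^2 + 27a^2h_0^4 +
5h_0^6)\,\sigma^6}{5\,(h_0+a)^6},$$
whose $h_0 \to a$ substitution yields $\delta h = (2/5)^{1/6}\sigma
\approx 0.858\sigma$; for the infinite rod
$$\left(h_0 - a\right)^6 = \frac{11\,(64a^6 + 432a^4h_0^2 + 504a^2h_0^4 +
105h_0^6)\,\sigma^6}{800\,(h_0+a)^6},$$
whose substitutions $h_0 = a$ and $h_0 = 2a$ bracket the gap between
$\approx 0.787\sigma$ (large spheres) and $\approx 0.824\sigma$ (small
spheres).  We note that these numbers follow from evaluating the
condition itself; the package never hard-codes the bound as a fraction.
For large spheres the bracket of $W(h)$ at $h_0 \approx a + 0.787\sigma$
scales as $\sqrt{a}$, giving $\Delta W \approx 4.48\,\epsilon
\sqrt{a/\sigma}$ at the reduced-unit densities.

## Parameters and conventions

| parameter | meaning | default | units |
|---|---|---|---|
| `epsilon` | LJ well depth | 1 | energy |
| `sigma` | LJ zero-crossing length | 1 | length |
| `a` | sphere radius | — | length |
| `rho_s` | sphere material density | 1 | length$^{-3}$ |
| `L` | rod length (`Inf` allowed) | — | length |
| `lambda` | rod line density | 1 | length$^{-1}$ |

All results are reported in reduced units (energies in $\epsilon$,
lengths in $\sigma$).  The densities default to the convention
$\lambda = 1\,\sigma^{-1}$, $\rho_s = 1\,\sigma^{-3}$ used throughout the
adhesion analysis; both enter the potential linearly, so other values
rescale every energy by $\lambda\rho_s$.

## Numerical choices

**Branch dispatch.**  `finite_rod_potential()` selects the tangent closed
form when $|h - a| \le 10^{-6}\sigma$ (and the rod does not straddle the
graze point; straddling configurations with a tiny gap are evaluated
exactly in extended precision instead).  The window is the exact-limit
form's domain of use: the tangent expression is exact at $h = a$ and its
error grows linearly in $|h - a|$, so a narrow window keeps that error at
the $10^{-5}$-relative level while avoiding any $0/0$ at the boundary.

**Cancellation control.**  Away from tangency the closed forms are
evaluated in doubles, but the terms of $G$ individually diverge like
$(h^2-a^2)^{-8}$ near $h = a$ (and partially cancel between endpoints at
large separations).  The double-precision evaluator returns, along with
the sum, the largest magnitude among its summed pieces; the ratio of the
two estimates the relative cancellation.  When it exceeds $10^6$ (so that
doubles would retain fewer than ~10 accurate digits) the endpoint
difference is recomputed by a C kernel in MPFR arbitrary-precision
arithmetic, starting from a precision derived from the measured
condition and escalating (up to 16384 bits) until two evaluations 64 bits
apart agree to $10^{-15}$ relative.  The result is flagged
`precision_mode = "extended"`.  Measuring the condition rather than
hard-coding a $|h-a|$ band also catches the slower cancellation of
well-separated configurations, where the paired arctangent/logarithm
forms (`atan` difference identity, `log1p` of the combined endpoint
ratio) are used to avoid most of the loss in the first place.

**Overflow-free large spheres.**  The infinite-rod potential and its
$h$-derivative are evaluated in a factored form: the bracket is written
as $\frac{1}{4u^{5/2}}\left(\frac{\sigma^6 n(x)}{160 u^3} - 1\right)$
with $u = h^2 - a^2$ and $n$ a cubic in the dimensionless ratio
$x = a^2/u$, with a log-space fallback.  No intermediate reaches the
double-precision overflow threshold even for $a = 10^4\sigma$ and
beyond, which is what the adhesion-scaling computation requires.

**Derivatives.**  $\partial W/\partial x_c$ is exact (endpoint values of
the integrand).  $\partial W/\partial h$ uses the closed form for
infinite rods; for finite rods it uses Richardson-extrapolated central
differences (three step sizes, $O(\text{step}^6)$) of the analytic
potential, with the step capped at one eighth of the sphere-rod clearance
so no probe configuration overlaps.  The accuracy contract, verified
against independent finite differences and quadratures in the test suite,
is $10^{-6}$ relative; the polar partials follow from the chain rule.

**Minimization.**  `find_h0()` minimizes over $\delta = h - a$ (not $h$),
which keeps the search well-conditioned for $a \gg \sigma$, using
bracketed golden-section/parabolic search on $[0.3, 3]\sigma$ with
geometric expansion of the upper edge if needed, to an interval tolerance
of $10^{-10}$.  The analytic (infinite rod) or finite-difference gradient
at the solution is recorded as a convergence certificate.  The
large-sphere asymptote of the scaling coefficient is estimated by
Richardson extrapolation in $1/a$ from the two largest radii, since the
finite-$a$ coefficient approaches its limit from below with an $O(1/a)$
correction.

**Quadrature oracle.**  The oracle integrates $\lambda\,U_{SP}$ along the
rod with adaptive Gauss-Kronrod panels, split at the point of closest
approach ($y = 0$) where the integrand peaks, at a default relative
tolerance of $10^{-11}$; infinite rods are truncated at $10^4\sigma$
(the neglected tail decays as the fifth inverse power of the truncation,
and doubling the truncation is verified to change nothing at tolerance).
The torque oracle integrates the lever-arm-weighted radial force density
using the closed-form $U_{SP}'$.  The oracle exists for verification
only; it is orders of magnitude slower than the closed forms.

## What the tests cover — and what they do not

The verification suite draws randomized configurations spanning all three
branches: radii $a \in [2, 12]\sigma$, lengths $L \in [0.5, 25]\sigma$,
gaps from $10^{-5.5}\sigma$ up to several $\sigma$, densities in
$[0.5, 2]$.  Across more than a thousand such draws the analytic
potential agrees with the quadrature oracle to $10^{-8}$ relative away
from tangency and $10^{-6}$ inside the near-tangency band, forces match
minus the numerical gradient and torques match the lever-arm quadrature
to $10^{-6}$, and continuity across $h = a$ is demonstrated from both
sides.  Configurations whose potential magnitude falls below
$10^{-8}\epsilon$ (razor-thin zero crossings) are redrawn, since relative
comparisons there measure only the oracle's own roundoff.  These checks
validate the mathematics and its numerical realization; they say nothing
about how well an LJ 12-6 continuum model describes any particular
experimental sphere-rod system — the Hamaker constant, densities and
length scales must be calibrated to the material at hand.

Problem sizes in the suite (about a thousand oracle comparisons, torque
quadratures at dozens of configurations, adhesion scans over a handful of
radii and lengths) were chosen so that the entire suite documents the
claimed tolerances in well under a minute on one core; all random draws
are seeded and deterministic.

## Design decisions

* **Angle convention:** $\theta$ is measured from the rod direction
  (O toward L) with origin at end O, $0 \le \theta \le \pi$; mirrored
  coordinates measured from the other end give the same potential
  (verified as a property).
* **Strict overlap test:** no tolerance is baked into the overlap
  predicate — the closed forms are finite arbitrarily close to contact;
  callers wanting a safety margin pass an inflated radius.
* **`L = Inf` routing:** `finite_rod_potential()` forwards infinite rods
  to the one-variable closed form and says so in the result's `branch`
  field rather than silently.
* **Derivative mechanism:** the $h$-derivative contract is the accuracy
  bound, not the formula; Richardson differences of the (arbitrarily
  accurate) analytic potential met the bound without the error surface of
  hand-differentiating the eight-term primitive, and the exact
  $x_c$-derivative plus chain-rule identities pin the remaining partials.
* **Command-line interface:** a thin `Rscript` wrapper
  (`inst/cli/rodsphere`, subcommands `potential | wrench | adhesion |
  verify`) over the exported functions; the package functions and the
  tabular (tibble in, tibble out) batch interfaces are the primary
  surface.

## Known limitations

* The rod is a material line: no cross-sectional radius, so no
  finite-radius cylinder effects.
* The interaction is the non-retarded LJ 12-6 integral; retarded
  ($1/r^7$) van der Waals tails and generalized LJ $2n$-$n$ exponents are
  out of scope.
* Rigid bodies only: no elasticity, dynamics, thermal or entropic
  corrections, and no many-body (multi-rod) systems or periodic
  boundaries.
* The extended-precision path costs microseconds per call but is only
  engaged where doubles demonstrably lose accuracy; code embedding the
  potential in a simulation loop should expect the standard path in the
  overwhelming majority of calls.
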