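Package: rodsphere
Title: Integrated Lennard-Jones Potential, Force and Torque for
    Sphere-Rod Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Closed-form Hamaker-integrated Lennard-Jones 12-6
    interaction between a solid sphere (a uniform continuum of LJ
    material points) and a thin rod (a material line of LJ points) in
    arbitrary three-dimensional configurations.  Provides the integrated
    potential for finite rods (separate branches for the rod axis passing
    outside, tangent to, or through the sphere), infinite rods and the
    point-rod limit, together with analytical forces and torques in local
    and global frames, an independent adaptive-quadrature oracle for
    verification, and an adhesion analysis of the sphere-rod equilibrium
    gap and its square-root-of-radius adhesion scaling.  Near-tangency
    configurations, where the closed forms suffer catastrophic floating
    point cancellation, are evaluated in arbitrary-precision arithmetic
    through the MPFR library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: GNU MPFR (libmpfr, with headers), GNU GMP
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
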