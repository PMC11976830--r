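#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy an adhesion result
#'
#' @param x A `rodsphere_adhesion` from [find_h0()].
#' @param ... Unused.
#' @return A one-row tibble with `a`, `L`, `h0`, `delta_h`, `DeltaW`.
#' @method tidy rodsphere_adhesion
#' @export
tidy.rodsphere_adhesion <- function(x, ...) {
  tibble::tibble(a = x$a, L = x$L, h0 = x$h0, delta_h = x$delta_h,
                 DeltaW = x$DeltaW)
}

#' @rdname tidy.rodsphere_adhesion
#' @return For `glance()`: a one-row tibble with the minimizer
#'   diagnostics (`W0`, `grad`, `converged`, `iterations`).
#' @method glance rodsphere_adhesion
#' @export
glance.rodsphere_adhesion <- function(x, ...) {
  tibble::tibble(W0 = x$W0, grad = x$grad, converged = x$converged,
                 iterations = x$iterations)
}

#' Tidy an adhesion-scaling result
#'
#' @param x A `rodsphere_scaling` from [adhesion_scaling()].
#' @param ... Unused.
#' @return The per-radius table (tibble with `a`, `h0`, `delta_h`,
#'   `DeltaW`, `coeff`).
#' @method tidy rodsphere_scaling
#' @export
tidy.rodsphere_scaling <- function(x, ...) {
  x$table
}

#' @rdname tidy.rodsphere_scaling
#' @return For `glance()`: a one-row tibble with the coefficient at the
#'   largest radius and the extrapolated asymptote.
#' @method glance rodsphere_scaling
#' @export
glance.rodsphere_scaling <- function(x, ...) {
  tibble::tibble(coefficient = x$coefficient, asymptote = x$asymptote,
                 n_radii = nrow(x$table), lambda = x$lambda, rho_s = x$rho_s)
}
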