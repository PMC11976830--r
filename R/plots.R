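#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a potential sweep
#'
#' Potential versus radial distance, colored by closed-form branch;
#' extended-precision rows are drawn as open points.
#'
#' @param object A `rodsphere_sweep` tibble from [run_potential_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rodsphere_sweep
#' @export
autoplot.rodsphere_sweep <- function(object, ...) {
  df <- object[!object$overlap, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$W,
                                   colour = .data$branch)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$precision_mode)) +
    ggplot2::scale_shape_manual(values = c(standard = 16, extended = 1)) +
    ggplot2::labs(x = expression(rho / sigma), y = expression(W / epsilon),
                  colour = "branch", shape = "precision") +
    ggplot2::theme_minimal()
}

#' Plot an adhesion scan
#'
#' Equilibrium gap versus rod length for each sphere radius, with the
#' closed-form infinite-rod bounds (~0.787 and ~0.824 sigma) as dashed
#' reference lines.
#'
#' @param object A `rodsphere_adhesion_scan` from [run_adhesion_scan()].
#' @param p An [lj_params()] used for the reference bounds.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rodsphere_adhesion_scan
#' @export
autoplot.rodsphere_adhesion_scan <- function(object, p = lj_params(), ...) {
  df <- object[is.finite(object$L), , drop = FALSE]
  lb <- solve_min_condition_infinite(1, p, "lower_bound")
  ub <- solve_min_condition_infinite(1, p, "upper_bound")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$L, y = .data$delta_h,
                                   colour = factor(.data$a))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(lb, ub), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(L / sigma),
                  y = expression(delta * h / sigma),
                  colour = "a") +
    ggplot2::theme_minimal()
}

#' Plot the adhesion scaling
#'
#' Adhesion depth versus the square root of the sphere radius; the dashed
#' line is the extrapolated large-sphere asymptote
#' `DeltaW = c * sqrt(a / sigma)`.
#'
#' @param object A `rodsphere_scaling` from [adhesion_scaling()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rodsphere_scaling
#' @export
autoplot.rodsphere_scaling <- function(object, ...) {
  df <- object$table
  df$sqrt_a <- sqrt(df$a)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sqrt_a, y = .data$DeltaW)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$asymptote, intercept = 0,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = expression(sqrt(a / sigma)),
                  y = expression(Delta * W / epsilon)) +
    ggplot2::theme_minimal()
}

#' Plot adhesion versus rod length
#'
#' @param object A `rodsphere_length_scan` from [adhesion_vs_length()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rodsphere_length_scan
#' @export
autoplot.rodsphere_length_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$L, y = .data$DeltaW)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$plateau)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(L / sigma),
                  y = expression(Delta * W / epsilon),
                  colour = "plateau") +
    ggplot2::theme_minimal()
}
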