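# ggplot2 autoplot methods for the result objects

#' Plot a basin-stability estimate
#'
#' Bar chart of the per-attractor estimates with Wilson intervals.
#'
#' @param object a [estimate_bs()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bs_estimate
#' @export
autoplot.bs_estimate <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$attractor, y = .data$p_hat)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::labs(x = NULL, y = "basin stability",
                  title = sprintf("%s | %s basis, n = %d, alpha = %g, T = %d",
                                  object$system, object$plan$basis$family,
                                  object$plan$n, object$plan$alpha, object$T)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a convergence scan
#'
#' Basin-stability estimates against the expansion order, one panel per
#' basis, one line per attractor; the chosen `n*` is marked.
#'
#' @param object a [convergence_scan()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bs_convergence
#' @export
autoplot.bs_convergence <- function(object, ...) {
  g <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$n, y = .data$p_hat,
                                    colour = .data$attractor)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~basis) +
    ggplot2::labs(x = "expansion order n", y = "basin stability") +
    ggplot2::theme_minimal()
  if (!is.na(object$n_star)) {
    g <- g + ggplot2::geom_vline(xintercept = object$n_star,
                                 linetype = "dashed", colour = "grey40")
  }
  g
}

#' Plot basin stability along a parameter grid
#'
#' @param object a [bs_vs_parameter()] result.
#' @param normalized plot the min-max normalized curves instead of raw
#'   estimates.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bs_profile
#' @export
autoplot.bs_profile <- function(object, normalized = FALSE, ...) {
  par <- attr(object, "parameter")
  y <- if (normalized && "p_norm" %in% names(object)) "p_norm" else "p_hat"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[par]], y = .data[[y]],
                               colour = .data$attractor,
                               linetype = .data$basis)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = par,
                  y = if (y == "p_norm") "normalized basin stability"
                      else "basin stability") +
    ggplot2::theme_minimal()
}

#' Plot a master-stability scan
#'
#' \eqn{\Lambda(\varepsilon)} with the zero line and the extracted stable
#' intervals shaded.
#'
#' @param object an [msf_scan()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot msf_result
#' @export
autoplot.msf_result <- function(object, ...) {
  g <- ggplot2::ggplot(object$table,
                       ggplot2::aes(x = .data$eps, y = .data$lambda)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(epsilon), y = expression(Lambda),
                  title = sprintf("master stability function, tau = %g",
                                  object$tau)) +
    ggplot2::theme_minimal()
  if (nrow(object$stable_intervals)) {
    g <- g + ggplot2::geom_rect(
      data = object$stable_intervals, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                   ymin = -Inf, ymax = 0),
      fill = "seagreen", alpha = 0.15)
  }
  g
}

#' Plot a network sweep
#'
#' Mean basin stability of the synchronization manifold (points and per-p
#' means) and median synchronizability `R` (rescaled, dashed) against the
#' rewiring probability.
#'
#' @param object a [network_bs_sweep()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bs_sweep
#' @export
autoplot.bs_sweep <- function(object, ...) {
  summ <- object |>
    dplyr::group_by(.data$p) |>
    dplyr::summarise(mean_bs = mean(.data$mean_bs),
                     med_R = stats::median(.data$R), .groups = "drop")
  r_scale <- max(summ$med_R[is.finite(summ$med_R)])
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_point(data = object,
                        ggplot2::aes(y = .data$mean_bs), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_bs), colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$med_R / r_scale),
                       colour = "steelblue", linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_continuous(
      name = "mean basin stability",
      sec.axis = ggplot2::sec_axis(~ . * r_scale, name = "median R")) +
    ggplot2::labs(x = "rewiring probability p") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
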