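# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the joint age-length (TL) distribution of T_MRCA-segments
#'
#' @param object a `tl_summary` from [tl_summaries()].
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.tl_summary <- function(object, ...) {
  df <- tibble::tibble(log10_age = object$log10_age,
                       log10_length = object$log10_length)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_age,
                                   y = .data$log10_length)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = expression(log[10] ~ T[MRCA] ~ "(generations)"),
                  y = expression(log[10] ~ "segment length (bp)"),
                  title = sprintf("TL-distribution (cov = %.3f)",
                                  object$covariance)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a segment-age transition matrix
#'
#' @param object a `tmatrix` from [tm_true()].
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.tmatrix <- function(object, ...) {
  m <- object$probs
  df <- tidyr::expand_grid(from = seq_len(nrow(m)), to = seq_len(ncol(m)))
  df$tp <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$tp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "tp", option = "inferno") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "age bin of segment n+1", y = "age bin of segment n",
                  title = "Transition matrix of segment ages") +
    ggplot2::theme_minimal()
}

#' Posterior distribution of a parameter
#'
#' Histogram of accepted draws with the prior support as x-limits (log10
#' scale for log-uniform parameters).
#'
#' @param object a `posterior_sample` from [abc_reject()].
#' @param parameter parameter to display.
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.posterior_sample <- function(object, parameter = "t_sigma", ...) {
  prior <- object$prior
  v <- .param_transform(prior, object$accepted[[parameter]], parameter)
  lo <- .param_transform(prior, prior$lower[prior$param == parameter], parameter)
  hi <- .param_transform(prior, prior$upper[prior$param == parameter], parameter)
  logscale <- prior$dist[prior$param == parameter] == "logunif"
  xlab <- if (logscale) sprintf("log10(%s)", parameter) else parameter
  ggplot2::ggplot(tibble::tibble(v = v), ggplot2::aes(x = .data$v)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white",
                            boundary = lo) +
    ggplot2::xlim(lo, hi) +
    ggplot2::labs(x = xlab, y = "accepted draws",
                  title = sprintf("Posterior of %s (tolerance %g)",
                                  parameter, object$tolerance)) +
    ggplot2::theme_minimal()
}

#' Model-choice performance across transition ages
#'
#' @param object a tibble from [validate_performance()].
#' @param threshold reference line for the target detection rate.
#' @param ... unused.
#' @return A ggplot.
#' @export
plot_validation <- function(object, threshold = 0.8, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = log10(.data$t_sigma),
                                       y = .data$frac_detected)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "goldenrod") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = expression(log[10] ~ t[sigma] ~ "(generations)"),
                  y = "fraction detected (BF >= threshold)",
                  title = "Model-choice performance") +
    ggplot2::theme_minimal()
}
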