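#' Tidy a Crooks report
#'
#' @param x a [crooks_report()].
#' @param ... unused.
#' @return the per-support-point tibble: `work`, `p_forward`, `p_backward`,
#'   `observed_ratio`, `predicted_ratio`, `defined`, `rel_error`.
#' @export
tidy.crooks_report <- function(x, ...) {
  x$table
}

#' One-row summary of a Crooks report
#'
#' @param x a [crooks_report()].
#' @param ... unused.
#' @return a one-row tibble: reversal kind, `k`, `delta_F`, whether `p0` is
#'   stationary for `M1`, the number of support points, how many ratios are
#'   defined, the worst relative error, and `holds`.
#' @export
glance.crooks_report <- function(x, ...) {
  tibble(
    kind = x$kind,
    k = x$k,
    delta_F = x$delta_F,
    beta = x$beta,
    p0_is_stationary_of_M1 = x$p0_is_stationary_of_M1,
    n_support = nrow(x$table),
    n_defined = sum(x$table$defined),
    max_rel_error = if (all(x$table$defined)) max(x$table$rel_error) else Inf,
    holds = x$holds
  )
}

#' Plot a work distribution
#'
#' Needle plot of the exact work atoms `P(W = w)`.
#'
#' @param object a [work_distribution()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.work_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$work, y = .data$prob)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$work, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "work (units of 1/β)", y = "probability",
                  title = "Exact work distribution") +
    ggplot2::theme_minimal()
}

#' Plot a Crooks report
#'
#' Observed forward/backward ratios against the predicted
#' `exp(beta (w - delta_F))` curve, on the log scale; undefined support
#' points (backward probability zero) are marked at the axis.
#'
#' @param object a [crooks_report()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.crooks_report <- function(object, ...) {
  d <- object$table
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$work)) +
    ggplot2::geom_line(ggplot2::aes(y = log(.data$predicted_ratio)),
                       linetype = "dashed") +
    ggplot2::geom_point(
      data = d[d$defined, ],
      ggplot2::aes(y = log(.data$observed_ratio)), size = 2
    ) +
    ggplot2::labs(
      x = "work w", y = "log ratio  log PF(w) / PB(-w + k)",
      title = sprintf("Crooks check (%s reversal, holds: %s)",
                      object$kind, object$holds)
    ) +
    ggplot2::theme_minimal()
  if (any(!d$defined)) {
    p <- p + ggplot2::geom_point(
      data = d[!d$defined, ],
      ggplot2::aes(y = 0), shape = 4, size = 3
    )
  }
  p
}
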