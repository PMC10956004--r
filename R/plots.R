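#' Plot a fitted price-to-walk curve
#'
#' Bids over session time with the fitted exponential
#' `k * exp(b * c * t)` overlaid; winning bids are drawn as circles and
#' losing bids as squares.
#'
#' @param object A [fit_price_to_walk()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ptw_fit
#' @export
autoplot.ptw_fit <- function(object, ...) {
  grid <- tibble(
    t = seq(min(object$data$t), max(object$data$t), length.out = 200),
  )
  grid$fitted <- object$k_hat * exp(object$effective_rate * grid$t)
  dat <- mutate(object$data, outcome = ifelse(.data$won, "winning", "losing"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$bid)) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$t, y = .data$fitted),
      colour = "#00798c", linewidth = 0.8
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$outcome), size = 2.2) +
    ggplot2::scale_shape_manual(values = c(winning = 16, losing = 15)) +
    ggplot2::labs(
      x = "Session time (min)", y = "Bid (USD)", shape = NULL,
      title = sprintf("Price to walk, %s", object$condition),
      subtitle = sprintf(
        "k = $%.2f, b = %.3f/min, c = %.2f, R² = %.2f",
        object$k_hat, object$b_hat, object$c, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ptw_fit
#' @param fit A `ptw_fit`.
#' @export
plot_price_to_walk <- function(fit, ...) autoplot(fit, ...)

#' Histogram of per-subject marginal values
#'
#' Positive MVs (value added to the wearer) in blue, negative MVs (costs
#' imposed) in red, faceted by comparison.
#'
#' @param mvs A [compute_mvs()] table.
#' @param binwidth Histogram bin width in MV percent.
#' @return A ggplot.
#' @export
plot_mv_histogram <- function(mvs, binwidth = 10) {
  dat <- mutate(mvs, sign = ifelse(.data$mv_percent >= 0, "positive", "negative"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mv_percent, fill = .data$sign)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0, colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(positive = "#2166ac", negative = "#b2182b"), guide = "none"
    ) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "Marginal value (% of baseline cumulative price)", y = "Subjects") +
    ggplot2::theme_minimal()
}
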