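# Marginal value: cumulative price-to-walk integrals and their differences.
# The fitted rate b is per *walked* minute (the win-rate scaling in the fit
# exists to make it so), so integrating k * exp(b * t) over [0, 30] prices a
# continuous 30-minute walking bout.

cum_price_closed_form <- function(k, rate, t1, t2) {
  if (abs(rate) < 1e-12) {
    k * (t2 - t1)
  } else {
    # expm1 keeps full precision through the small-rate neighbourhood
    (k / rate) * exp(rate * t1) * expm1(rate * (t2 - t1))
  }
}

extract_kb <- function(fit) {
  if (inherits(fit, "ptw_fit")) {
    list(k = fit$k_hat, b = fit$b_hat, condition = fit$condition)
  } else if (is.list(fit) && all(c("k", "b") %in% names(fit))) {
    list(k = fit$k, b = fit$b, condition = fit$condition %||% NA_character_)
  } else {
    abort_validation("`fit` must be a ptw_fit or a list with elements `k` and `b`")
  }
}

#' Cumulative price to walk
#'
#' Integrates a price-to-walk curve `k * exp(b * t)` over a walking-time
#' window, in closed form: `(k/b) * (exp(b*t2) - exp(b*t1))`, with the limit
#' `k * (t2 - t1)` when `|b| < 1e-12`. The default 0-30 min window roughly
#' matches the average time a participant walks in one session.
#'
#' @param fit A [fit_price_to_walk()] object, or a `list(k =, b =)` of curve
#'   parameters (USD, per-minute rate).
#' @param t1,t2 Integration bounds in minutes (`t2 > t1`).
#' @return Cumulative price in USD.
#' @examples
#' cumulative_price(list(k = 0.5, b = 0.04)) # 29.00
#' @export
cumulative_price <- function(fit, t1 = 0, t2 = 30) {
  p <- extract_kb(fit)
  check_number(t1, "t1")
  check_number(t2, "t2")
  if (t2 <= t1) abort_validation("`t2` must be > `t1`")
  cum_price_closed_form(p$k, p$b, t1, t2)
}

#' Marginal value between two conditions
#'
#' The marginal value (MV) is the difference of cumulative prices,
#' baseline minus comparison: a *positive* MV means the comparison condition
#' is cheaper to walk in, i.e. the device (or assistance) added value. The
#' percentage form normalises by a baseline cumulative price, which removes
#' the wide between-subject differences in the absolute valuation of time.
#'
#' @param fit_baseline,fit_comparison Price-to-walk fits (or `list(k=, b=)`)
#'   for the baseline (condition 1) and comparison (condition 2).
#' @param t1,t2 Integration bounds in minutes.
#' @param normalizer Optional fit whose cumulative price is used as the
#'   percentage denominator; defaults to `fit_baseline`. Useful when two
#'   device conditions are compared but percentages should stay expressed
#'   relative to the subject's no-device baseline.
#' @return A one-row tibble: `mv_usd`, `mv_percent`, `baseline_condition`,
#'   `comparison_condition`, `baseline_cumulative`, `comparison_cumulative`,
#'   `t1`, `t2`.
#' @examples
#' marginal_value(list(k = 0.5, b = 0.04), list(k = 0.5, b = 0.03))
#' @export
marginal_value <- function(fit_baseline, fit_comparison, t1 = 0, t2 = 30,
                           normalizer = NULL) {
  b <- extract_kb(fit_baseline)
  cmp <- extract_kb(fit_comparison)
  cum_base <- cumulative_price(fit_baseline, t1, t2)
  cum_cmp <- cumulative_price(fit_comparison, t1, t2)
  cum_norm <- if (is.null(normalizer)) cum_base else cumulative_price(normalizer, t1, t2)
  if (cum_norm <= 0) {
    abort_validation("cannot normalise: baseline cumulative price is not positive")
  }
  mv_usd <- cum_base - cum_cmp
  tibble(
    mv_usd = mv_usd,
    mv_percent = 100 * mv_usd / cum_norm,
    baseline_condition = b$condition,
    comparison_condition = cmp$condition,
    baseline_cumulative = cum_base,
    comparison_cumulative = cum_cmp,
    t1 = t1, t2 = t2
  )
}

#' Convert a cumulative price to an hourly rate
#'
#' @param cumulative Cumulative price in USD over the window.
#' @param t1,t2 Window bounds in minutes (`t2 > t1`).
#' @return Rate in USD per hour.
#' @examples
#' hourly_rate(29.25) # 58.50/h over a 30-min window
#' @export
hourly_rate <- function(cumulative, t1 = 0, t2 = 30) {
  check_number(cumulative, "cumulative")
  if (t2 - t1 <= 0) abort_validation("window must have positive width")
  cumulative / ((t2 - t1) / 60)
}

#' Convert a marginal-value percentage to dollars per hour
#'
#' Multiplies a baseline hourly rate by an MV percentage, giving the change
#' in hourly value relative to the baseline condition.
#'
#' @param rate Baseline rate in USD per hour.
#' @param mv_percent Marginal value as a percentage of the baseline.
#' @return USD per hour added (or, if negative, cost imposed).
#' @examples
#' mv_to_hourly(58.50, -31.8) # about -$18.60/h
#' @export
mv_to_hourly <- function(rate, mv_percent) {
  check_number(rate, "rate")
  check_number(mv_percent, "mv_percent")
  rate * mv_percent / 100
}
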