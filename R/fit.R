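#' Win rate of a session
#'
#' The fraction of auctions the human won. It enters the price-to-walk model
#' as the scaling factor `c`, which converts session time into expected
#' walking time and thereby controls for how much of the session each
#' participant actually walked.
#'
#' @param log A [run_session()] log.
#' @return Win rate in `[0, 1]`.
#' @export
compute_win_rate <- function(log) {
  stopifnot(inherits(log, "session_log"))
  hum <- log$records[log$records$bidder_id == "human", ]
  if (nrow(hum) == 0L) abort_validation("empty session log")
  mean(hum$won)
}

#' Fit the price-to-walk curve
#'
#' Fits the first-order exponential price-to-walk model
#' `Y(t) = k * exp(b * c * t)` to all of a session's human bids (winning and
#' losing alike) by least squares, where `t` is session time at each auction,
#' `c` is the session win rate (fixed, not fitted), and `k`, `b` are free.
#' Because `c` rescales session time toward walking time, `b` is the fatigue
#' rate per *walked* minute.
#'
#' The optimum is found by profiling: for a fixed rate the optimal `k` has
#' the closed form `sum(y*u) / sum(u^2)` with `u = exp(b*c*t)`, so the
#' problem reduces to a one-dimensional search over `b` (coarse grid plus
#' golden-section refinement to relative tolerance ~1e-10). With all-constant
#' bids the fit degenerates to `b = 0` with `R^2 = 1` by convention (zero
#' residual, zero total sum of squares).
#'
#' @param log A [run_session()] log (>= 3 bids, at least one win).
#' @param nonneg_rate Constrain `b >= 0` (bids invariably trend upwards with
#'   fatigue); set `FALSE` to allow a decaying curve.
#' @param rate_max Upper bound of the rate search, per minute.
#' @return An object of class `ptw_fit`: `k_hat` (USD), `b_hat` (per walked
#'   minute), `c` (win rate), `effective_rate` (`b_hat * c`, per session
#'   minute), `r_squared`, `rss`, `n_bids`, `condition`, `subject_id`,
#'   `session_id`, and `data` (tibble of `t`, `bid`, `won`).
#' @examples
#' h <- human_agent(k_true = 0.5, b_true = 0.04)
#' log <- run_session(h, make_default_robo_cohort(3), session_config(seed = 7))
#' fit <- fit_price_to_walk(log)
#' glance(fit)
#' @export
fit_price_to_walk <- function(log, nonneg_rate = TRUE, rate_max = 1) {
  stopifnot(inherits(log, "session_log"))
  hum <- log$records[log$records$bidder_id == "human", ]
  y <- hum$bid
  t <- hum$t_start
  if (length(y) < 3L) abort_validation("need at least 3 bids to fit a price-to-walk curve")
  cc <- mean(hum$won)
  if (cc == 0) {
    abort_validation("degenerate model: the participant never walked (win rate 0)")
  }

  rss_at <- function(b) {
    u <- exp(b * cc * t)
    k <- sum(y * u) / sum(u * u)
    sum((y - k * u)^2)
  }

  lo <- if (nonneg_rate) 0 else -rate_max
  grid <- seq(lo, rate_max, length.out = 241L)
  vals <- vapply(grid, rss_at, numeric(1))
  i0 <- which.min(vals)
  bracket <- c(grid[max(i0 - 1L, 1L)], grid[min(i0 + 1L, length(grid))])
  opt <- optimize(rss_at, bracket, tol = 1e-10)
  b_hat <- if (opt$objective <= vals[i0]) opt$minimum else grid[i0]

  u <- exp(b_hat * cc * t)
  k_hat <- sum(y * u) / sum(u * u)
  rss <- sum((y - k_hat * u)^2)
  sst <- sum((y - mean(y))^2)
  r_squared <- if (sst > 0) 1 - rss / sst else if (rss < 1e-12) 1 else NA_real_

  structure(
    list(
      k_hat = k_hat, b_hat = b_hat, c = cc, effective_rate = b_hat * cc,
      r_squared = r_squared, rss = rss, n_bids = length(y),
      condition = log$condition, subject_id = log$subject_id,
      session_id = log$session_id,
      data = tibble(t = t, bid = y, won = hum$won)
    ),
    class = "ptw_fit"
  )
}

#' @export
print.ptw_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<ptw_fit> price-to-walk curve, condition %s (%d bids)\n",
      "  Y(t) = %.4f * exp(%.5f * %.3f * t)   [k * exp(b * c * t)]\n",
      "  R^2 = %.3f\n"
    ),
    x$condition, x$n_bids, x$k_hat, x$b_hat, x$c, x$r_squared
  ))
  invisible(x)
}

#' @method tidy ptw_fit
#' @export
tidy.ptw_fit <- function(x, ...) {
  tibble(
    term = c("k", "b"),
    estimate = c(x$k_hat, x$b_hat),
    unit = c("USD", "per walked minute")
  )
}

#' @method glance ptw_fit
#' @export
glance.ptw_fit <- function(x, ...) {
  tibble(
    subject_id = x$subject_id, session_id = x$session_id,
    condition = x$condition,
    k_hat = x$k_hat, b_hat = x$b_hat, c = x$c,
    effective_rate = x$effective_rate,
    r_squared = x$r_squared, n_bids = x$n_bids
  )
}
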