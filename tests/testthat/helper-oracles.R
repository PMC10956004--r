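# Independent oracles and fixture builders used across the suite.

# Brute-force 2-D grid search for the price-to-walk least-squares problem.
# Independent of the package's profiled optimizer: evaluates the RSS over an
# explicit (k, b) grid and returns the best grid point. RSS(k) for fixed b is
# expanded algebraically (C - 2kB + k^2 A) so the k grid can be swept as a
# vector, but every value corresponds to a direct grid evaluation.
grid_search_fit <- function(y, t, c,
                            k_grid = seq(0.01, 10, length.out = 1500),
                            b_grid = seq(0, 0.2, length.out = 1501)) {
  best <- list(rss = Inf, k = NA, b = NA)
  C <- sum(y^2)
  for (b in b_grid) {
    u <- exp(b * c * t)
    A <- sum(u * u)
    B <- sum(y * u)
    rss_k <- C - 2 * k_grid * B + k_grid^2 * A
    i <- which.min(rss_k)
    if (rss_k[i] < best$rss) best <- list(rss = rss_k[i], k = k_grid[i], b = b)
  }
  best
}

# Adaptive-quadrature oracle for the cumulative price integral.
quadrature_cum_price <- function(k, beta, t1, t2) {
  stats::integrate(function(t) k * exp(beta * t), t1, t2,
                   rel.tol = 1e-13, abs.tol = 0, subdivisions = 1000L)$value
}

# Build a session_log directly from a human bid sequence and win pattern,
# without running the simulator: a single robo opponent is given bids
# consistent with the outcome (above the human's bid when the human wins,
# below when it loses).
make_fixture_log <- function(bids, won, interval = 2,
                             condition = "walking-no-exo",
                             subject_id = "S01", session_id = NULL) {
  stopifnot(length(bids) == length(won))
  n <- length(bids)
  robo <- ifelse(won, round(bids + 0.25, 2), pmax(round(bids - 0.05, 2), 0.01))
  clearing <- ifelse(won, robo, bids) # second-lowest of the two
  col_won <- as.vector(rbind(won, !won))
  col_walked <- rep(won, each = 2)
  records <- tibble::tibble(
    interval_index = rep(seq_len(n), each = 2),
    t_start = rep((seq_len(n) - 1) * interval, each = 2),
    bidder_id = rep(c("human", "robo1"), n),
    bid = as.vector(rbind(bids, robo)),
    won = col_won,
    clearing_price = rep(clearing, each = 2),
    human_walked = col_walked
  )
  structure(
    list(
      subject_id = subject_id,
      session_id = session_id %||% paste0(subject_id, "_", condition, "_1"),
      condition = condition,
      config = session_config(
        interval_minutes = interval,
        duration_lo = n * interval, duration_hi = n * interval,
        n_robo = 1, condition = condition
      ),
      scheduled_minutes = n * interval,
      records = records,
      human_earnings = sum(clearing[won]),
      human_walk_minutes = interval * sum(won)
    ),
    class = "session_log"
  )
}

# Honest exponential bid sequence on the walking-time clock: bid i is
# k * exp(b * walked_minutes_before_i).
honest_bids <- function(k, b, won, interval = 2) {
  walked <- c(0, cumsum(won[-length(won)])) * interval
  k * exp(b * walked)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
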