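#' Session configuration
#'
#' One session is a series of sealed-bid reverse Vickrey auctions, each
#' selling one 2-minute walking bout, run for a randomly drawn total duration
#' (uniform between `duration_lo` and `duration_hi` minutes; the randomness
#' discourages waiting out the other bidders). With the defaults a session
#' contains floor(U(50, 70) / 2) = 25 to 35 auctions.
#'
#' @param interval_minutes Length of one walking bout (minutes).
#' @param duration_lo,duration_hi Bounds of the uniform session duration
#'   (minutes).
#' @param n_robo Number of robo-bidder opponents.
#' @param condition Condition label attached to the log; behaviour enters
#'   only through the agent parameters.
#' @param seed Optional integer seed; if supplied, `run_session()` seeds the
#'   RNG before simulating so the log is exactly reproducible.
#' @return An object of class `session_config`.
#' @export
session_config <- function(interval_minutes = 2, duration_lo = 50, duration_hi = 70,
                           n_robo = 3, condition = "walking-no-exo", seed = NULL) {
  check_number(interval_minutes, "interval_minutes", min = 1e-9)
  check_number(duration_lo, "duration_lo", min = 0)
  check_number(duration_hi, "duration_hi", min = 0)
  if (duration_lo > duration_hi) {
    abort_validation("`duration_lo` must be <= `duration_hi`")
  }
  check_number(n_robo, "n_robo", min = 1)
  structure(
    list(
      interval_minutes = interval_minutes,
      duration_lo = duration_lo, duration_hi = duration_hi,
      n_robo = as.integer(n_robo), condition = condition, seed = seed
    ),
    class = "session_config"
  )
}

#' Draw the scheduled session duration
#'
#' @param config A [session_config()].
#' @return Scheduled duration in minutes, uniform on
#'   `[duration_lo, duration_hi]`.
#' @export
draw_session_duration <- function(config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  runif(1L, config$duration_lo, config$duration_hi)
}

#' Simulate one full auction session
#'
#' Runs the sequential reverse Vickrey auction protocol for one subject and
#' condition: each interval, sealed bids are collected from the human agent
#' and every robo-bidder, the auction is settled second-price, the winner's
#' state advances (the winner walks), and only the clearing price is
#' disclosed to the human agent. Partial trailing intervals are dropped
#' (a bid buys a full bout), so the auction count is
#' `floor(scheduled / interval_minutes)`.
#'
#' @param human A [human_agent()].
#' @param robos A list of [robo_bidder()] (or a single one).
#' @param config A [session_config()].
#' @param subject_id,session_id Identifiers stamped on the log.
#' @return An object of class `session_log`: a list with `subject_id`,
#'   `session_id`, `condition`, `config`, `scheduled_minutes`, `records`
#'   (a tibble with one row per bidder per interval: `interval_index`,
#'   `t_start`, `bidder_id`, `bid`, `won`, `clearing_price`,
#'   `human_walked`), `human_earnings` and `human_walk_minutes`.
#' @examples
#' h <- human_agent(k_true = 0.5, b_true = 0.04)
#' set.seed(1)
#' log <- run_session(h, make_default_robo_cohort(3), session_config(seed = 1))
#' session_summary(log)
#' @export
run_session <- function(human, robos, config = session_config(),
                        subject_id = "S01", session_id = NULL) {
  stopifnot(inherits(human, "human_agent"), inherits(config, "session_config"))
  if (inherits(robos, "robo_bidder")) robos <- list(robos)
  if (length(robos) < 1L || !all(vapply(robos, inherits, logical(1), "robo_bidder"))) {
    abort_validation("`robos` must be a non-empty list of robo_bidder objects")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  scheduled <- draw_session_duration(config)
  n_int <- floor(scheduled / config$interval_minutes)
  if (n_int < 1L) abort_validation("scheduled duration shorter than one interval")

  robo_ids <- sprintf("robo%d", seq_along(robos))
  ids <- c("human", robo_ids)
  nb <- length(ids)
  rstates <- lapply(robos, function(p) robo_state())
  hstate <- human_state()

  total <- n_int * nb
  col_interval <- integer(total)
  col_t <- numeric(total)
  col_bidder <- character(total)
  col_bid <- numeric(total)
  col_won <- logical(total)
  col_clearing <- numeric(total)
  col_walked <- logical(total)

  for (i in seq_len(n_int)) {
    t_start <- (i - 1) * config$interval_minutes
    hbid <- human_bid(human, hstate)
    rbids <- vapply(
      seq_along(robos),
      function(j) robo_bid(robos[[j]], rstates[[j]]),
      numeric(1)
    )
    amts <- c(hbid, rbids)
    core <- settle_core(to_cents(amts), "selling")
    clearing <- from_cents(core$clearing)
    won <- seq_len(nb) == core$winner
    walked <- won[1L]

    idx <- ((i - 1L) * nb + 1L):(i * nb)
    col_interval[idx] <- i
    col_t[idx] <- t_start
    col_bidder[idx] <- ids
    col_bid[idx] <- amts
    col_won[idx] <- won
    col_clearing[idx] <- clearing
    col_walked[idx] <- walked

    for (j in seq_along(robos)) {
      rstates[[j]] <- advance_robo_state(rstates[[j]], won[j + 1L], bid = rbids[j])
    }
    hstate <- advance_human_state(hstate, walked, clearing,
                                  config$interval_minutes)
  }

  records <- tibble(
    interval_index = col_interval, t_start = col_t, bidder_id = col_bidder,
    bid = col_bid, won = col_won, clearing_price = col_clearing,
    human_walked = col_walked
  )
  human_rows <- records$bidder_id == "human"
  structure(
    list(
      subject_id = subject_id,
      session_id = session_id %||% paste0(subject_id, "_", config$condition, "_1"),
      condition = config$condition,
      config = config,
      scheduled_minutes = scheduled,
      records = records,
      human_earnings = sum(records$clearing_price[human_rows & records$won]),
      human_walk_minutes = hstate$minutes_walked
    ),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  s <- session_summary(x)
  cat(sprintf(
    paste0(
      "<session_log> %s, condition %s\n",
      "  %d auctions over %.1f scheduled min; %d wins (win rate %.2f)\n",
      "  walked %.0f min, earned $%.2f, mean bid $%.2f\n"
    ),
    x$session_id, x$condition, s$n_auctions, x$scheduled_minutes,
    s$wins, s$win_rate, s$walk_minutes, s$earnings, s$mean_bid
  ))
  invisible(x)
}

#' Summarise one session log
#'
#' @param log A [run_session()] log.
#' @return A one-row tibble: `n_auctions`, `wins`, `win_rate`,
#'   `walk_minutes`, `earnings` and `mean_bid` (over the human's bids).
#' @export
session_summary <- function(log) {
  stopifnot(inherits(log, "session_log"))
  hum <- log$records[log$records$bidder_id == "human", ]
  if (nrow(hum) == 0L) abort_validation("empty session log")
  wins <- sum(hum$won)
  tibble(
    subject_id = log$subject_id,
    session_id = log$session_id,
    condition = log$condition,
    n_auctions = nrow(hum),
    wins = wins,
    win_rate = wins / nrow(hum),
    walk_minutes = log$human_walk_minutes,
    earnings = log$human_earnings,
    mean_bid = mean(hum$bid)
  )
}
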