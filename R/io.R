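# Bid-log CSV format: one row per bidder per interval, fixed header,
# UTF-8, '.' decimal separator, USD amounts as fixed two-decimal strings so
# that write -> read round-trips are exact at cent resolution.

bid_log_columns <- c(
  "session_id", "condition", "interval_index", "t_start_min", "bidder_id",
  "bid_usd", "won", "clearing_price_usd", "human_walked"
)

#' Write a session log to a bid-log CSV
#'
#' @param log A [run_session()] log.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bid_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  r <- log$records
  out <- tibble(
    session_id = log$session_id,
    condition = log$condition,
    interval_index = r$interval_index,
    t_start_min = r$t_start,
    bidder_id = r$bidder_id,
    bid_usd = sprintf("%.2f", r$bid),
    won = as.integer(r$won),
    clearing_price_usd = sprintf("%.2f", r$clearing_price),
    human_walked = as.integer(r$human_walked)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a bid-log CSV back into a session log
#'
#' Validates the file (required columns, exactly one winner per interval,
#' one row per bidder per interval, positive amounts) and reconstructs the
#' session log. The interval length is recovered from the time stamps and
#' the scheduled duration is taken as `n_intervals * interval_minutes`
#' unless a metadata sidecar (see [write_session_meta()]) supplies the exact
#' value.
#'
#' @param path Bid-log CSV path.
#' @param meta Optional session metadata list from [read_session_meta()].
#' @return A `session_log`.
#' @export
read_bid_log <- function(path, meta = NULL) {
  if (!file.exists(path)) abort_validation(sprintf("no such file: %s", path))
  df <- tryCatch(
    suppressWarnings(readr::read_csv(path, col_types = readr::cols(
      session_id = readr::col_character(),
      condition = readr::col_character(),
      interval_index = readr::col_integer(),
      t_start_min = readr::col_double(),
      bidder_id = readr::col_character(),
      bid_usd = readr::col_double(),
      won = readr::col_integer(),
      clearing_price_usd = readr::col_double(),
      human_walked = readr::col_integer()
    ), progress = FALSE)),
    error = function(e) abort_validation(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  )
  missing <- setdiff(bid_log_columns, names(df))
  if (length(missing) > 0L) {
    abort_validation(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) abort_validation(sprintf("empty bid log: %s", path))
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    abort_validation(sprintf(
      "malformed rows in '%s' (first at line %d): %s",
      path, probs$row[1] + 1L, probs$expected[1]
    ))
  }
  if (any(df$bid_usd < 0.01)) {
    bad <- which(df$bid_usd < 0.01)[1]
    abort_validation(sprintf("non-positive bid amount at data row %d", bad))
  }
  winners <- tapply(df$won, df$interval_index, sum)
  bad <- names(winners)[winners != 1L]
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "interval %s must have exactly one winner", paste(bad, collapse = ", ")
    ))
  }
  dup <- df |>
    dplyr::count(.data$interval_index, .data$bidder_id) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort_validation(sprintf(
      "duplicate bidder '%s' in interval %d", dup$bidder_id[1], dup$interval_index[1]
    ))
  }

  intervals <- sort(unique(df$interval_index))
  t_by_interval <- df$t_start_min[match(intervals, df$interval_index)]
  interval_minutes <- if (length(intervals) > 1L) {
    diff(t_by_interval)[1]
  } else {
    meta$interval_min %||% 2
  }
  n_int <- length(intervals)
  n_robo <- length(unique(df$bidder_id)) - 1L

  records <- tibble(
    interval_index = df$interval_index,
    t_start = df$t_start_min,
    bidder_id = df$bidder_id,
    bid = df$bid_usd,
    won = df$won == 1L,
    clearing_price = df$clearing_price_usd,
    human_walked = df$human_walked == 1L
  )
  hum <- records[records$bidder_id == "human", ]
  cfg <- session_config(
    interval_minutes = interval_minutes,
    duration_lo = meta$scheduled_duration_min %||% (n_int * interval_minutes),
    duration_hi = meta$scheduled_duration_min %||% (n_int * interval_minutes),
    n_robo = max(n_robo, 1L),
    condition = df$condition[1],
    seed = meta$seed
  )
  structure(
    list(
      subject_id = meta$subject_id %||% NA_character_,
      session_id = df$session_id[1],
      condition = df$condition[1],
      config = cfg,
      scheduled_minutes = meta$scheduled_duration_min %||% (n_int * interval_minutes),
      records = records,
      human_earnings = sum(hum$clearing_price[hum$won]),
      human_walk_minutes = interval_minutes * sum(hum$won)
    ),
    class = "session_log"
  )
}

#' Write / read the session metadata sidecar
#'
#' A YAML key-value document carrying everything needed to re-simulate the
#' session bit-exactly: identifiers, condition, exact scheduled duration,
#' interval length, seed, and (optionally) the agent parameter blocks.
#'
#' @param log A `session_log`.
#' @param path Output `.yaml` path.
#' @param human,robos Optional agent parameter objects to embed.
#' @return `path` invisibly (write); a named list (read).
#' @export
write_session_meta <- function(log, path, human = NULL, robos = NULL) {
  stopifnot(inherits(log, "session_log"))
  meta <- list(
    subject_id = log$subject_id,
    session_id = log$session_id,
    condition = log$condition,
    scheduled_duration_min = log$scheduled_minutes,
    interval_min = log$config$interval_minutes,
    n_robo = log$config$n_robo,
    seed = log$config$seed
  )
  if (!is.null(human)) meta$human <- unclass(human)
  if (!is.null(robos)) {
    if (inherits(robos, "robo_bidder")) robos <- list(robos)
    meta$robo_bidders <- lapply(robos, unclass)
  }
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' @rdname write_session_meta
#' @export
read_session_meta <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("no such file: %s", path))
  yaml::read_yaml(path)
}

#' Write a cohort's bid logs and ground truth to a directory
#'
#' @param cohort A `ptw_cohort`.
#' @param dir Output directory (created if needed). One CSV per session plus
#'   `ground_truth.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ptw_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (log in cohort$sessions$log) {
    write_bid_log(log, file.path(dir, paste0(log$session_id, ".csv")))
  }
  readr::write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' Read a directory of bid logs
#'
#' @param dir Directory containing bid-log CSVs (as written by
#'   [write_cohort()]; `ground_truth.tsv` is ignored).
#' @return A list of `session_log` objects.
#' @export
read_cohort_logs <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) abort_validation(sprintf("no bid-log CSVs in %s", dir))
  logs <- lapply(files, read_bid_log)
  for (i in seq_along(logs)) {
    logs[[i]]$subject_id <- sub("_.*$", "", logs[[i]]$session_id)
  }
  logs
}
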