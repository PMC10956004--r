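#' Fit price-to-walk curves for a set of sessions
#'
#' @param x A `ptw_cohort` from [simulate_cohort()], a list of session logs,
#'   or a single log.
#' @param t1,t2 Cumulative-price window in minutes.
#' @return A tibble with one row per session: identifiers, `k_hat`, `b_hat`,
#'   `c`, `r_squared`, `n_bids`, `cumulative` (USD over `[t1, t2]`) and a
#'   `fit` list-column of `ptw_fit` objects.
#' @export
fit_sessions <- function(x, t1 = 0, t2 = 30) {
  logs <- if (inherits(x, "ptw_cohort")) {
    x$sessions$log
  } else if (inherits(x, "session_log")) {
    list(x)
  } else {
    x
  }
  if (!all(vapply(logs, inherits, logical(1), "session_log"))) {
    abort_validation("`x` must be a ptw_cohort, a session_log, or a list of session_logs")
  }
  fits <- purrr::map(logs, fit_price_to_walk)
  out <- purrr::map_dfr(fits, glance)
  out$cumulative <- vapply(fits, cumulative_price, numeric(1), t1 = t1, t2 = t2)
  if (inherits(x, "ptw_cohort")) {
    out$repeat_index <- x$sessions$repeat_index
  } else {
    out <- out |>
      group_by(.data$subject_id, .data$condition) |>
      mutate(repeat_index = row_number()) |>
      ungroup()
  }
  out$fit <- fits
  out
}

#' Per-subject marginal values across conditions
#'
#' Computes, for each subject, the MV of every non-baseline condition
#' against the baseline, and — when both a powered and an unpowered device
#' condition are present — the MV of the assistance alone (unpowered vs
#' powered), still normalised by the subject's baseline cumulative price.
#' Only first sessions (`repeat_index == 1`) enter; repeats are reserved for
#' reliability analysis.
#'
#' @param fits A [fit_sessions()] table.
#' @param baseline Baseline condition label.
#' @param t1,t2 Integration bounds in minutes.
#' @param powered,unpowered Condition labels used to form the
#'   assistance-alone contrast; set either to `NULL` to skip it.
#' @return A tibble with one row per subject x comparison: `subject_id`,
#'   `comparison`, `baseline_condition`, `comparison_condition`, `mv_usd`,
#'   `mv_percent`.
#' @export
compute_mvs <- function(fits, baseline = "walking-no-exo", t1 = 0, t2 = 30,
                        powered = "exo-powered", unpowered = "exo-powered-off") {
  first <- fits[fits$repeat_index == 1L, ]
  if (!baseline %in% first$condition) {
    abort_validation(sprintf("no session has the baseline condition '%s'", baseline))
  }
  base_tbl <- first[first$condition == baseline, ]
  others <- unique(first$condition[first$condition != baseline])

  one_subject <- function(sid) {
    bfit <- base_tbl$fit[base_tbl$subject_id == sid][[1]]
    rows <- list()
    for (cond in others) {
      sel <- first$condition == cond & first$subject_id == sid
      if (!any(sel)) next
      cfit <- first$fit[sel][[1]]
      mv <- marginal_value(bfit, cfit, t1 = t1, t2 = t2)
      mv$comparison <- paste(cond, "vs", baseline)
      rows <- c(rows, list(mv))
    }
    if (!is.null(powered) && !is.null(unpowered)) {
      sel_p <- first$condition == powered & first$subject_id == sid
      sel_u <- first$condition == unpowered & first$subject_id == sid
      if (any(sel_p) && any(sel_u)) {
        mv <- marginal_value(first$fit[sel_u][[1]], first$fit[sel_p][[1]],
                             t1 = t1, t2 = t2, normalizer = bfit)
        mv$comparison <- "assistance-alone"
        rows <- c(rows, list(mv))
      }
    }
    if (length(rows) == 0L) return(NULL)
    mutate(bind_rows(rows), subject_id = sid)
  }

  out <- purrr::map_dfr(base_tbl$subject_id, one_subject)
  select(
    out, "subject_id", "comparison", "baseline_condition",
    "comparison_condition", "mv_usd", "mv_percent",
    "baseline_cumulative", "comparison_cumulative", "t1", "t2"
  )
}

#' End-to-end cohort analysis
#'
#' Runs the full analysis pipeline on a cohort of session logs: price-to-walk
#' fits, per-subject marginal values, one-sample t-tests per comparison,
#' test-retest reliability and MDC from repeated baseline sessions (when
#' present), and responder classification of the device-vs-baseline MVs
#' against the MDC threshold.
#'
#' @param x A `ptw_cohort`, a list of session logs, or a [fit_sessions()]
#'   table.
#' @param baseline Baseline condition label.
#' @param t1,t2 Cumulative-price window in minutes.
#' @param confidence Confidence level for the MDC.
#' @param responder_threshold Threshold (MV percent) for responder labels;
#'   defaults to the computed MDC, or stays `NULL` (no classification) when
#'   no repeats are available and no threshold is given.
#' @param responder_comparison Which comparison's MVs to classify.
#' @return An object of class `cohort_analysis` with elements `fits`, `mvs`,
#'   `tests`, `reliability`, `mdc_pct`, `responders` and `params`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 3, seed = 42))
#' analyze_cohort(cohort)
#' @export
analyze_cohort <- function(x, baseline = "walking-no-exo", t1 = 0, t2 = 30,
                           confidence = 0.95, responder_threshold = NULL,
                           responder_comparison = NULL) {
  fits <- if (is.data.frame(x) && "fit" %in% names(x)) x else fit_sessions(x, t1 = t1, t2 = t2)
  mvs <- compute_mvs(fits, baseline = baseline, t1 = t1, t2 = t2)

  tests <- mvs |>
    group_by(.data$comparison) |>
    summarise(res = list(one_sample_t(.data$mv_percent)), .groups = "drop")
  tests <- bind_rows(
    purrr::map2(tests$comparison, tests$res, function(cmp, r) mutate(r, comparison = cmp))
  ) |>
    select("comparison", dplyr::everything())

  rel <- NULL
  mdc_pct <- NULL
  base_repeats <- fits[fits$condition == baseline, ]
  n_rep <- table(base_repeats$subject_id)
  if (any(n_rep >= 2L)) {
    keep <- names(n_rep)[n_rep >= 2L]
    rel <- repeatability(
      base_repeats[base_repeats$subject_id %in% keep, c("subject_id", "cumulative")]
    )
    mdc_pct <- mdc(rel$intra_subject_sd_pct, confidence = confidence)
  }

  threshold <- responder_threshold %||% mdc_pct
  responders <- NULL
  if (!is.null(threshold)) {
    cmp <- responder_comparison %||% grep("vs", unique(mvs$comparison), value = TRUE)[1]
    responders <- classify_responders(
      mvs[mvs$comparison == cmp, c("subject_id", "mv_percent")],
      threshold_pct = threshold
    )
    responders$comparison <- cmp
  }

  structure(
    list(
      fits = fits, mvs = mvs, tests = tests, reliability = rel,
      mdc_pct = mdc_pct, responders = responders,
      params = list(baseline = baseline, t1 = t1, t2 = t2,
                    confidence = confidence, threshold = threshold)
    ),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf(
    "<cohort_analysis> %d sessions, %d subjects; window [%g, %g] min\n",
    nrow(x$fits), length(unique(x$fits$subject_id)), x$params$t1, x$params$t2
  ))
  cat(sprintf("  mean fit R^2: %.3f\n", mean(x$fits$r_squared)))
  for (i in seq_len(nrow(x$tests))) {
    r <- x$tests[i, ]
    cat(sprintf(
      "  %s: mean MV %.1f%% (SD %.1f, SEM %.1f, n=%d), t(%d)=%.2f, p=%.3f, d=%.2f\n",
      r$comparison, r$mean, r$sd, r$sem, r$n, r$df, r$t, r$p_value, r$cohens_d
    ))
  }
  if (!is.null(x$mdc_pct)) {
    cat(sprintf(
      "  reliability: intra-subject SD %.2f%%, MDC %.1f%% at %.0f%% confidence\n",
      x$reliability$intra_subject_sd_pct, x$mdc_pct, 100 * x$params$confidence
    ))
  }
  if (!is.null(x$responders)) {
    counts <- table(x$responders$label)
    cat(sprintf(
      "  responders (%s, threshold %.1f%%): %d positive, %d negative, %d indeterminate\n",
      x$responders$comparison[1], x$params$threshold,
      counts[["positive"]], counts[["negative"]], counts[["indeterminate"]]
    ))
  }
  invisible(x)
}

#' @method tidy cohort_analysis
#' @export
tidy.cohort_analysis <- function(x, ...) x$tests

#' @method glance cohort_analysis
#' @export
glance.cohort_analysis <- function(x, ...) {
  tibble(
    n_sessions = nrow(x$fits),
    n_subjects = length(unique(x$fits$subject_id)),
    mean_r_squared = mean(x$fits$r_squared),
    mdc_pct = x$mdc_pct %||% NA_real_,
    n_positive = if (is.null(x$responders)) NA_integer_ else sum(x$responders$label == "positive"),
    n_negative = if (is.null(x$responders)) NA_integer_ else sum(x$responders$label == "negative"),
    t1 = x$params$t1, t2 = x$params$t2
  )
}
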