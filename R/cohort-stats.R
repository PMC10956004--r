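# Cohort-level inference and test-retest reliability for MV measurements.
# Sample SDs use the n-1 denominator throughout (standard for small-N human
# studies).

#' Standard error of the mean
#'
#' @param sd Sample standard deviation (any unit; typically MV percent).
#' @param n Sample size (>= 1).
#' @return `sd / sqrt(n)`.
#' @examples
#' sem(31.14, 16) # 7.785
#' @export
sem <- function(sd, n) {
  check_number(sd, "sd", min = 0)
  check_number(n, "n", min = 1)
  sd / sqrt(n)
}

#' One-sample two-tailed t-test with effect size
#'
#' Tests whether a set of per-subject values (typically MV percentages) has
#' mean zero, and reports the one-sample Cohen's d (`mean / sd`, no
#' small-sample correction).
#'
#' @param values Numeric vector, `n >= 2`, non-constant.
#' @param mu Null mean (default 0).
#' @return A one-row tibble: `n`, `mean`, `sd`, `sem`, `t`, `df`, `p_value`,
#'   `cohens_d`.
#' @examples
#' one_sample_t(c(1, 2, 3))
#' @export
one_sample_t <- function(values, mu = 0) {
  if (!is.numeric(values) || length(values) < 2L) {
    abort_validation("`values` must be a numeric vector with n >= 2")
  }
  s <- sd(values)
  if (s == 0) abort_validation("degenerate test: values have zero standard deviation")
  ht <- t.test(values, mu = mu)
  n <- length(values)
  m <- mean(values)
  tibble(
    n = n, mean = m, sd = s, sem = s / sqrt(n),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, cohens_d = (m - mu) / s
  )
}

#' Intra-subject repeatability of cumulative prices
#'
#' For each subject with repeated measurements, computes the SD of the
#' repeats as a percentage of that subject's mean (a coefficient of
#' variation), then averages across subjects. This is the day-to-day
#' fluctuation in the value demanded to walk, the noise floor against which
#' condition effects must be judged.
#'
#' @param data A data frame with one row per repeated measurement.
#' @param subject,value Column names (strings) of the subject id and the
#'   repeated measurement (e.g. cumulative price in USD).
#' @return A list of class `ptw_reliability`: `per_subject` (tibble with
#'   `subject_id`, `n_repeats`, `mean`, `sd`, `cv_pct`) and
#'   `intra_subject_sd_pct` (their average). Subjects with fewer than two
#'   repeats are dropped with a warning; a zero subject mean is an error.
#' @examples
#' repeatability(data.frame(subject_id = c("a", "a"), cumulative = c(29, 31)))
#' @export
repeatability <- function(data, subject = "subject_id", value = "cumulative") {
  if (!is.data.frame(data) || !all(c(subject, value) %in% names(data))) {
    abort_validation(sprintf("`data` must contain columns `%s` and `%s`", subject, value))
  }
  per <- data |>
    group_by(subject_id = .data[[subject]]) |>
    summarise(
      n_repeats = n(),
      mean = mean(.data[[value]]),
      sd = sd(.data[[value]]),
      .groups = "drop"
    )
  dropped <- per$subject_id[per$n_repeats < 2L]
  if (length(dropped) > 0L) {
    warn(sprintf(
      "excluding %d subject(s) with fewer than 2 repeats: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
    per <- per[per$n_repeats >= 2L, ]
  }
  if (nrow(per) == 0L) abort_validation("no subject has >= 2 repeated measurements")
  if (any(per$mean == 0)) abort_validation("a subject has zero mean; cannot express SD as a percentage")
  per$cv_pct <- 100 * per$sd / per$mean
  structure(
    list(per_subject = per, intra_subject_sd_pct = mean(per$cv_pct)),
    class = "ptw_reliability"
  )
}

#' @export
print.ptw_reliability <- function(x, ...) {
  cat(sprintf(
    "<ptw_reliability> %d subjects with repeats; average intra-subject SD %.2f%% of subject mean\n",
    nrow(x$per_subject), x$intra_subject_sd_pct
  ))
  invisible(x)
}

#' Minimum detectable change
#'
#' The smallest change between two measurements not attributable to chance
#' at a given two-sided confidence: `z * sqrt(2) * sd`, where `sd` is the
#' intra-subject (test-retest) SD and the `sqrt(2)` accounts for the change
#' being a difference of two noisy measurements. At 95% confidence the
#' multiplier is `1.959964 * sqrt(2) = 2.7718`.
#'
#' @param intra_subject_sd_pct Intra-subject SD, in percent of subject mean.
#' @param confidence Two-sided confidence level in (0, 1).
#' @return MDC in the same units as `intra_subject_sd_pct`.
#' @examples
#' mdc(3.4) # 9.42
#' @export
mdc <- function(intra_subject_sd_pct, confidence = 0.95) {
  check_number(intra_subject_sd_pct, "intra_subject_sd_pct", min = 0)
  if (!is_scalar_number(confidence) || confidence <= 0 || confidence >= 1) {
    abort_validation("`confidence` must be in (0, 1)")
  }
  qnorm(1 - (1 - confidence) / 2) * sqrt(2) * intra_subject_sd_pct
}

#' Classify responders against a detectability threshold
#'
#' Labels each subject `positive` if their MV exceeds `+threshold_pct`
#' (strict), `negative` if below `-threshold_pct` (strict), and
#' `indeterminate` otherwise, i.e. when the measured effect is within the
#' band that day-to-day variability alone could produce.
#'
#' @param data A data frame with one row per subject.
#' @param threshold_pct Threshold in MV percent (>= 0); typically the
#'   computed [mdc()].
#' @param subject,value Column names of the subject id and MV percent.
#' @return The input rows with a `label` factor column
#'   (`positive`/`negative`/`indeterminate`).
#' @examples
#' classify_responders(
#'   data.frame(subject_id = c("a", "b", "c"), mv_percent = c(27.8, 5.8, -31.8)),
#'   threshold_pct = 9.4
#' )
#' @export
classify_responders <- function(data, threshold_pct,
                                subject = "subject_id", value = "mv_percent") {
  check_number(threshold_pct, "threshold_pct", min = 0)
  if (!is.data.frame(data) || !all(c(subject, value) %in% names(data))) {
    abort_validation(sprintf("`data` must contain columns `%s` and `%s`", subject, value))
  }
  mv <- data[[value]]
  label <- ifelse(mv > threshold_pct, "positive",
                  ifelse(mv < -threshold_pct, "negative", "indeterminate"))
  out <- as_tibble(data)
  out$label <- factor(label, levels = c("positive", "negative", "indeterminate"))
  out$threshold_pct <- threshold_pct
  out
}
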