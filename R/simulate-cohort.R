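#' True marginal value implied by generating parameters
#'
#' Closed-form MV percentage between two exponential price-to-walk curves
#' given their generating parameters: `100 * (I_base - I_cond) / I_base`
#' with `I = (k/b) * (exp(b*t2) - exp(b*t1))`. Vectorised over parameters.
#'
#' @param k_base,b_base Baseline-condition generating parameters.
#' @param k_cond,b_cond Comparison-condition generating parameters.
#' @param t1,t2 Integration bounds in minutes.
#' @return True MV in percent of the baseline cumulative price.
#' @examples
#' true_mv(0.5, 0.04, 0.5, 0.03) # 16.1%
#' @export
true_mv <- function(k_base, b_base, k_cond, b_cond, t1 = 0, t2 = 30) {
  i_base <- mapply(cum_price_closed_form, k_base, b_base, t1, t2)
  i_cond <- mapply(cum_price_closed_form, k_cond, b_cond, t1, t2)
  100 * (i_base - i_cond) / i_base
}

#' Specify a synthetic cohort study
#'
#' Defines subjects x conditions x repeat sessions for a fully synthetic
#' study with known ground truth. Each subject draws honest-bidder
#' parameters `k_true ~ U(k_range)` (USD) and `b_true ~ U(b_range)` (per
#' walked minute). Condition effects act multiplicatively on the fatigue
#' rate `b_true` by default (perceived difficulty), jittered per
#' subject-condition on the log scale by `condition_sd` to create the
#' between-subject spread of responses seen in practice; the baseline
#' condition (multipliers exactly 1) is never jittered. An additive-`k`
#' effect mode is available for robustness experiments.
#'
#' @param n_subjects Number of subjects.
#' @param conditions A data frame with columns `condition`, `n_subjects`
#'   (how many subjects, taken in id order, undergo it), and `b_multiplier`
#'   (and optionally `k_multiplier`). Defaults to a baseline plus a powered
#'   device condition for every subject.
#' @param repeaters Optional data frame with columns `subject_id` and
#'   `extra_sessions`: extra repeat sessions of `baseline_condition` for
#'   test-retest reliability.
#' @param baseline_condition Name of the baseline condition.
#' @param k_range,b_range Subject-parameter priors.
#' @param condition_sd Log-scale SD of the per-subject condition multiplier
#'   jitter.
#' @param effect_on `"b"` (multiplicative on the rate) or `"k"`
#'   (multiplicative on the initial price).
#' @param bid_noise_sd Human bid-noise SD in USD.
#' @param cent_rounding Round human bids to whole cents (see
#'   [human_agent()]).
#' @param n_robo,robo_k_range,robo_b_range Robo-bidder opponents per session
#'   and their prior (see [make_default_robo_cohort()]).
#' @param duration_lo,duration_hi Session duration bounds in minutes.
#' @param seed Optional integer seed making the whole cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 16,
                        conditions = NULL,
                        repeaters = NULL,
                        baseline_condition = "walking-no-exo",
                        k_range = c(0.25, 0.75),
                        b_range = c(0.02, 0.06),
                        condition_sd = 0.30,
                        effect_on = c("b", "k"),
                        bid_noise_sd = 0.05,
                        cent_rounding = TRUE,
                        n_robo = 3,
                        robo_k_range = c(0.40, 1.00),
                        robo_b_range = c(0.15, 0.30),
                        duration_lo = 50, duration_hi = 70,
                        seed = NULL) {
  effect_on <- match.arg(effect_on)
  check_number(n_subjects, "n_subjects", min = 1)
  n_subjects <- as.integer(n_subjects)
  if (is.null(conditions)) {
    conditions <- tibble(
      condition = c("walking-no-exo", "exo-powered"),
      n_subjects = c(n_subjects, n_subjects),
      b_multiplier = c(1, 0.92)
    )
  }
  conditions <- as_tibble(conditions)
  if (!all(c("condition", "n_subjects", "b_multiplier") %in% names(conditions))) {
    abort_validation("`conditions` needs columns condition, n_subjects, b_multiplier")
  }
  if (!"k_multiplier" %in% names(conditions)) conditions$k_multiplier <- 1
  if (any(conditions$b_multiplier <= 0) || any(conditions$k_multiplier <= 0)) {
    abort_validation("condition multipliers must be > 0")
  }
  if (!baseline_condition %in% conditions$condition) {
    abort_validation("`baseline_condition` must appear in `conditions`")
  }
  if (any(conditions$n_subjects > n_subjects)) {
    abort_validation("a condition cannot have more participants than `n_subjects`")
  }
  check_number(condition_sd, "condition_sd", min = 0)
  check_number(bid_noise_sd, "bid_noise_sd", min = 0)
  structure(
    list(
      n_subjects = n_subjects, conditions = conditions,
      repeaters = if (is.null(repeaters)) NULL else as_tibble(repeaters),
      baseline_condition = baseline_condition,
      k_range = k_range, b_range = b_range,
      condition_sd = condition_sd, effect_on = effect_on,
      bid_noise_sd = bid_noise_sd, cent_rounding = isTRUE(cent_rounding),
      n_robo = as.integer(n_robo),
      robo_k_range = robo_k_range, robo_b_range = robo_b_range,
      duration_lo = duration_lo, duration_hi = duration_hi,
      seed = seed
    ),
    class = "cohort_spec"
  )
}

#' The reference study design
#'
#' A 16-subject cohort: all subjects in the baseline (`walking-no-exo`) and
#' powered-device (`exo-powered`) conditions, the first ten additionally in
#' the unpowered-device (`exo-powered-off`) condition, and four further
#' subjects repeating the baseline condition (three of them twice more, one
#' once more) for test-retest reliability — 42 condition sessions, 49 logs
#' in total with the repeats.
#'
#' @param seed Optional integer seed.
#' @param repeaters Include the repeat sessions (default `TRUE`).
#' @param ... Passed on to [cohort_spec()] (e.g. `bid_noise_sd`).
#' @return A `cohort_spec`.
#' @export
reference_design_spec <- function(seed = NULL, repeaters = TRUE, ...) {
  conditions <- tibble(
    condition = c("walking-no-exo", "exo-powered", "exo-powered-off"),
    n_subjects = c(16L, 16L, 10L),
    b_multiplier = c(1, 0.92, 1.375)
  )
  rep_tbl <- if (isTRUE(repeaters)) {
    tibble(
      subject_id = c("S11", "S12", "S13", "S14"),
      extra_sessions = c(2L, 2L, 2L, 1L)
    )
  } else {
    NULL
  }
  cohort_spec(
    n_subjects = 16, conditions = conditions, repeaters = rep_tbl,
    seed = seed, ...
  )
}

#' Simulate a full synthetic cohort
#'
#' Draws subject parameters from the cohort specification's priors, realises per-condition
#' parameters, and runs one complete auction session (via [run_session()],
#' against a freshly drawn default robo cohort) for every subject x
#' condition x repeat, each with its own derived seed. Ground truth (the
#' realised generating parameters and the closed-form true MV of every
#' condition against the baseline) is returned alongside, so that the whole
#' downstream pipeline can be checked against known answers.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `ptw_cohort`: a list with `sessions` (tibble
#'   with `subject_id`, `condition`, `repeat_index`, `seed` and a `log`
#'   list-column of session logs), `ground_truth` (tibble with `subject_id`,
#'   `condition`, realised `k_true`, `b_true` and `true_mv_percent` vs the
#'   baseline) and `spec`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 2, seed = 1))
#' cohort$ground_truth
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)

  subj_ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  k_true <- runif(spec$n_subjects, spec$k_range[1], spec$k_range[2])
  b_true <- runif(spec$n_subjects, spec$b_range[1], spec$b_range[2])

  gt <- purrr::pmap_dfr(spec$conditions, function(condition, n_subjects,
                                                  b_multiplier, k_multiplier) {
    idx <- seq_len(n_subjects)
    is_baseline <- b_multiplier == 1 && k_multiplier == 1
    jitter <- if (is_baseline || spec$condition_sd == 0) {
      rep(1, n_subjects)
    } else {
      exp(rnorm(n_subjects, 0, spec$condition_sd))
    }
    if (spec$effect_on == "b") {
      k_cond <- k_true[idx] * k_multiplier
      b_cond <- b_true[idx] * b_multiplier * jitter
    } else {
      k_cond <- k_true[idx] * k_multiplier * jitter
      b_cond <- b_true[idx] * b_multiplier
    }
    tibble(subject_id = subj_ids[idx], condition = condition,
           k_true = k_cond, b_true = b_cond)
  })
  base_gt <- gt[gt$condition == spec$baseline_condition, ]
  gt <- left_join(
    gt,
    select(base_gt, "subject_id", k_base = "k_true", b_base = "b_true"),
    by = "subject_id"
  )
  gt$true_mv_percent <- true_mv(gt$k_base, gt$b_base, gt$k_true, gt$b_true)
  gt <- select(gt, -"k_base", -"b_base")

  sessions <- mutate(select(gt, "subject_id", "condition"), repeat_index = 1L)
  if (!is.null(spec$repeaters) && nrow(spec$repeaters) > 0L) {
    extra <- purrr::pmap_dfr(spec$repeaters, function(subject_id, extra_sessions) {
      tibble(
        subject_id = subject_id, condition = spec$baseline_condition,
        repeat_index = 1L + seq_len(extra_sessions)
      )
    })
    if (!all(extra$subject_id %in% subj_ids)) {
      abort_validation("`repeaters` names a subject that is not in the cohort")
    }
    sessions <- bind_rows(sessions, extra)
  }
  sessions <- arrange(sessions, .data$subject_id, .data$condition, .data$repeat_index)
  sessions$seed <- sample.int(.Machine$integer.max, nrow(sessions))

  key <- paste(gt$subject_id, gt$condition, sep = "\r")

  sessions$log <- purrr::pmap(
    list(sessions$subject_id, sessions$condition, sessions$repeat_index, sessions$seed),
    function(sid, cond, rep_i, seed_i) {
      row <- gt[key == paste(sid, cond, sep = "\r"), ]
      set.seed(seed_i)
      robos <- make_default_robo_cohort(
        spec$n_robo,
        k_range = spec$robo_k_range, b_range = spec$robo_b_range
      )
      human <- human_agent(row$k_true, row$b_true,
                           bid_noise_sd = spec$bid_noise_sd,
                           cent_rounding = spec$cent_rounding)
      cfg <- session_config(
        duration_lo = spec$duration_lo, duration_hi = spec$duration_hi,
        n_robo = spec$n_robo, condition = cond
      )
      run_session(human, robos, cfg, subject_id = sid,
                  session_id = sprintf("%s_%s_%d", sid, cond, rep_i))
    }
  )

  structure(
    list(sessions = sessions, ground_truth = gt, spec = spec),
    class = "ptw_cohort"
  )
}

#' @export
print.ptw_cohort <- function(x, ...) {
  cat(sprintf(
    "<ptw_cohort> %d subjects, %d sessions across %d conditions\n",
    length(unique(x$sessions$subject_id)), nrow(x$sessions),
    length(unique(x$sessions$condition))
  ))
  invisible(x)
}
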