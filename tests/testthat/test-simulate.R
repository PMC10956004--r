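test_that("true MV follows the closed-form integrals of the generating curves", {
  expect_equal(true_mv(0.5, 0.04, 0.5, 0.04), 0)
  expect_equal(true_mv(0.5, 0.04, 0.5, 0.03), 16.1, tolerance = 1e-2)
  expect_equal(
    true_mv(0.5, 0.04, 0.5, 0.03),
    100 * (quadrature_cum_price(0.5, 0.04, 0, 30) - quadrature_cum_price(0.5, 0.03, 0, 30)) /
      quadrature_cum_price(0.5, 0.04, 0, 30),
    tolerance = 1e-9
  )
  # doubling k with the same b doubles the integral: MV = -100%
  expect_equal(true_mv(0.5, 0.04, 1.0, 0.04), -100)
})

test_that("the reference design produces 42 condition sessions, 49 with repeats", {
  co <- simulate_cohort(reference_design_spec(seed = 2, repeaters = FALSE))
  expect_equal(nrow(co$sessions), 42)
  counts <- table(co$sessions$condition)
  expect_equal(
    as.integer(counts[c("walking-no-exo", "exo-powered", "exo-powered-off")]),
    c(16L, 16L, 10L)
  )
  co <- simulate_cohort(reference_design_spec(seed = 2))
  expect_equal(nrow(co$sessions), 49)
  expect_equal(sum(co$sessions$repeat_index > 1), 7)
  # ground truth: baseline MV against itself is zero
  base <- co$ground_truth[co$ground_truth$condition == "walking-no-exo", ]
  expect_true(all(base$true_mv_percent == 0))
})

test_that("repeat sessions get distinct seeds; a fixed spec seed reproduces everything", {
  spec <- cohort_spec(
    n_subjects = 1,
    repeaters = data.frame(subject_id = "S01", extra_sessions = 2L),
    seed = 5
  )
  co <- simulate_cohort(spec)
  base_logs <- co$sessions[co$sessions$condition == "walking-no-exo", ]
  expect_equal(nrow(base_logs), 3)
  expect_equal(length(unique(base_logs$seed)), 3)

  co2 <- simulate_cohort(spec)
  expect_identical(co$ground_truth, co2$ground_truth)
  expect_identical(co$sessions$log, co2$sessions$log)
})

test_that("noiseless uncontested sessions recover the generating parameters", {
  spec <- cohort_spec(
    n_subjects = 4, bid_noise_sd = 0, cent_rounding = FALSE,
    condition_sd = 0,
    robo_k_range = c(100, 120), robo_b_range = c(0, 0),
    seed = 9
  )
  co <- simulate_cohort(spec)
  fits <- fit_sessions(co)
  m <- merge(fits, co$ground_truth, by = c("subject_id", "condition"))
  expect_true(all(m$c == 1))
  expect_lt(max(abs(m$k_hat - m$k_true)), 1e-6)
  expect_lt(max(abs(m$b_hat - m$b_true)), 1e-6)
  mvs <- compute_mvs(fits)
  gt <- co$ground_truth[co$ground_truth$condition == "exo-powered", ]
  m2 <- merge(mvs, gt, by = "subject_id")
  expect_lt(max(abs(m2$mv_percent - m2$true_mv_percent)), 1e-6)
})

test_that("estimated MVs are unbiased for the cohort mean under competitive bidding", {
  # noiseless bids but competitive robo opponents: per-subject MVs carry
  # approximation error from the walked-time vs scaled-session-time clock,
  # but the cohort mean stays close to the ground-truth mean
  bias <- vapply(1:10, function(s) {
    co <- simulate_cohort(cohort_spec(n_subjects = 8, bid_noise_sd = 0, seed = 300 + s))
    mvs <- compute_mvs(fit_sessions(co))
    est <- mvs[mvs$comparison == "exo-powered vs walking-no-exo", ]
    gt <- co$ground_truth[co$ground_truth$condition == "exo-powered", ]
    m <- merge(est, gt, by = "subject_id")
    mean(m$mv_percent - m$true_mv_percent)
  }, numeric(1))
  expect_lt(abs(mean(bias)), 2)
})

test_that("intra-subject variability shrinks as bid noise vanishes", {
  rel_at_noise <- function(noise) {
    spec <- cohort_spec(
      n_subjects = 2,
      repeaters = data.frame(subject_id = c("S01", "S02"), extra_sessions = c(2L, 2L)),
      bid_noise_sd = noise, seed = 77
    )
    an <- analyze_cohort(simulate_cohort(spec), responder_threshold = 9.4)
    an$reliability$intra_subject_sd_pct
  }
  noisy <- rel_at_noise(0.10)
  quiet <- rel_at_noise(0.01)
  expect_lt(quiet, noisy)
})

test_that("cohort specs validate their structure", {
  expect_error(
    cohort_spec(conditions = data.frame(condition = "x", n_subjects = 1, b_multiplier = 0)),
    class = "ptw_validation_error"
  )
  expect_error(
    cohort_spec(n_subjects = 4, conditions = data.frame(
      condition = c("walking-no-exo", "y"), n_subjects = c(4, 9), b_multiplier = c(1, 1)
    )),
    class = "ptw_validation_error"
  )
  expect_error(
    simulate_cohort(cohort_spec(
      n_subjects = 1,
      repeaters = data.frame(subject_id = "S99", extra_sessions = 1L),
      seed = 1
    )),
    class = "ptw_validation_error"
  )
})
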