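test_that("robo bids follow k * exp(b * t_k), cent-rounded", {
  p <- robo_bidder(k_init = 0.60, b_rate = 0.08, noise_sd = 0)
  expect_equal(robo_bid(p, robo_state(0)), 0.60)
  # 0.60 * exp(0.8) = 1.33533, cent-rounded (checked against direct evaluation)
  expect_equal(robo_bid(p, robo_state(10)), round(0.60 * exp(0.8), 2))
  expect_equal(robo_bid(p, robo_state(10)), 1.34)
  # expected bid non-decreasing in intervals walked
  bids <- vapply(0:20, function(t) robo_bid(p, robo_state(t)), numeric(1))
  expect_true(all(diff(bids) >= 0))
})

test_that("robo bid noise has the contracted mean and spread", {
  p <- robo_bidder(k_init = 0.60, b_rate = 0.08, noise_sd = 0.01)
  st <- robo_state(10)
  set.seed(123)
  draws <- replicate(1e5, robo_bid(p, st))
  det <- 0.60 * exp(0.8)
  expect_lt(abs(mean(draws) - det), 0.001)
  # cent rounding adds ~step^2/12 variance on top of the 0.01 noise
  expect_lt(abs(sd(draws) - 0.01) / 0.01, 0.10)
})

test_that("robo state advances only on wins", {
  st <- robo_state(3)
  expect_identical(advance_robo_state(st, won = TRUE)$intervals_walked, 4L)
  expect_identical(advance_robo_state(st, won = FALSE)$intervals_walked, 3L)
  st <- robo_state(0)
  for (i in 1:5) st <- advance_robo_state(st, won = TRUE)
  expect_identical(st$intervals_walked, 5L)
})

test_that("losing robo bids are frozen without noise, literal mode repeats verbatim", {
  p <- robo_bidder(0.75, 0.2, noise_sd = 0)
  st <- robo_state(4)
  expect_identical(robo_bid(p, st), robo_bid(p, st))

  pl <- robo_bidder(0.75, 0.2, noise_sd = 0.01, literal_constant = TRUE)
  set.seed(5)
  st <- robo_state(4)
  first <- robo_bid(pl, st)
  st <- advance_robo_state(st, won = FALSE, bid = first)
  expect_identical(robo_bid(pl, st), first)
  # after a win the deterministic component moves, so a fresh bid is drawn
  st2 <- advance_robo_state(st, won = TRUE, bid = first)
  expect_false(identical(robo_bid(pl, st2), first))
})

test_that("honest human bids sit exactly on the fatigue curve", {
  h <- human_agent(k_true = 0.50, b_true = 0.05)
  expect_equal(human_bid(h, human_state(0)), 0.50)
  expect_equal(human_bid(h, human_state(20)), round(0.50 * exp(1.0), 2))
  expect_equal(human_bid(h, human_state(20)), 1.36)
  # deterministic part is stateless: same query twice, same bid
  st <- human_state(14)
  expect_identical(human_bid(h, st), human_bid(h, st))
  # continuous mode returns the unrounded value
  hc <- human_agent(0.50, 0.05, cent_rounding = FALSE)
  expect_equal(human_bid(hc, human_state(20)), 0.50 * exp(1.0), tolerance = 1e-12)
  # whole noiseless trajectory lies on k * exp(b * w)
  won <- rep(c(TRUE, FALSE), 10)
  st <- human_state()
  for (i in seq_along(won)) {
    w <- st$minutes_walked
    expect_equal(human_bid(hc, st), 0.50 * exp(0.05 * w), tolerance = 1e-12)
    st <- advance_human_state(st, won[i], clearing_price = 1)
  }
})

test_that("human state accumulates walking time and the disclosed prices", {
  st <- human_state()
  expect_equal(advance_human_state(st, TRUE, 0.9)$minutes_walked, 2)
  expect_equal(advance_human_state(st, FALSE, 0.9)$minutes_walked, 0)
  won <- c(rep(TRUE, 7), rep(FALSE, 5))
  for (i in seq_along(won)) st <- advance_human_state(st, won[i], 0.5 + i / 100)
  expect_equal(st$minutes_walked, 14)
  expect_length(st$observed_clearing_prices, 12)
})

test_that("fixed-markup strategy shifts the honest bid by a constant", {
  hm <- human_agent(0.50, 0.05, strategy = "fixed-markup", markup = 0.25)
  expect_equal(human_bid(hm, human_state(0)), 0.75)
  expect_equal(human_bid(hm, human_state(20)), round(0.50 * exp(1) + 0.25, 2))
})

test_that("default robo cohort draws valid, reproducible parameter sets", {
  set.seed(99)
  cohort <- make_default_robo_cohort(3)
  expect_length(cohort, 3)
  ks <- vapply(cohort, `[[`, numeric(1), "k_init")
  expect_true(all(ks >= 0.10 & ks <= 5.00))
  expect_gt(length(unique(ks)), 1)

  set.seed(99)
  again <- make_default_robo_cohort(3)
  expect_identical(cohort, again)

  expect_length(make_default_robo_cohort(1), 1)
  expect_error(make_default_robo_cohort(0), class = "ptw_validation_error")
})

test_that("agent constructors validate their parameters", {
  expect_error(robo_bidder(0, 0.1), class = "ptw_validation_error")
  expect_error(robo_bidder(0.5, -1), class = "ptw_validation_error")
  expect_error(human_agent(0.5, 0.05, bid_noise_sd = -0.01),
               class = "ptw_validation_error")
})
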