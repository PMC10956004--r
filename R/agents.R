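#' Robo-bidder parameters
#'
#' A robo-bidder is a computerized auction opponent whose deterministic price
#' rises exponentially with the number of intervals it has walked (i.e. won):
#' `y = k_init * exp(b_rate * t_k) + sigma`, where `t_k` counts the
#' robo-bidder's auction wins and `sigma` is Gaussian noise (zero mean,
#' default SD $0.01) added so that a human opponent cannot intuit the bid
#' model. A losing robo-bidder's deterministic component is frozen; by
#' default fresh noise is still drawn each auction, while
#' `literal_constant = TRUE` re-submits the exact previous number instead.
#'
#' @param k_init Initial price in USD (>= 0.01).
#' @param b_rate Exponential growth rate per walked interval (>= 0).
#' @param noise_sd Standard deviation of the additive bid noise in USD.
#' @param literal_constant If `TRUE`, a robo-bidder that did not win repeats
#'   its previous bid verbatim (no fresh noise).
#' @return An object of class `robo_bidder`.
#' @export
robo_bidder <- function(k_init, b_rate, noise_sd = 0.01, literal_constant = FALSE) {
  check_number(k_init, "k_init", min = 0.01)
  check_number(b_rate, "b_rate", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  structure(
    list(
      k_init = k_init, b_rate = b_rate, noise_sd = noise_sd,
      literal_constant = isTRUE(literal_constant)
    ),
    class = "robo_bidder"
  )
}

#' Robo-bidder state
#'
#' Tracks the number of intervals the robo-bidder has walked (its win count,
#' which drives the exponential), plus bookkeeping for the literal-constant
#' repeat mode.
#'
#' @param intervals_walked Number of auctions won so far.
#' @param last_bid Last submitted bid (USD), `NA` before the first auction.
#' @param last_t Value of `intervals_walked` when `last_bid` was submitted.
#' @return An object of class `robo_state`.
#' @export
robo_state <- function(intervals_walked = 0L, last_bid = NA_real_, last_t = NA_integer_) {
  check_number(intervals_walked, "intervals_walked", min = 0)
  structure(
    list(
      intervals_walked = as.integer(intervals_walked),
      last_bid = last_bid, last_t = last_t
    ),
    class = "robo_state"
  )
}

#' Generate one robo-bidder bid
#'
#' Evaluates `k_init * exp(b_rate * intervals_walked)`, adds Gaussian noise,
#' rounds to whole cents and floors at $0.01. The deterministic component
#' depends only on the walked-interval count, so a robo-bidder that keeps
#' losing keeps the same expected price.
#'
#' @param params A [robo_bidder()].
#' @param state A [robo_state()].
#' @return A single bid in USD.
#' @export
robo_bid <- function(params, state) {
  stopifnot(inherits(params, "robo_bidder"), inherits(state, "robo_state"))
  if (params$literal_constant && !is.na(state$last_bid) &&
      identical(state$last_t, state$intervals_walked)) {
    return(state$last_bid)
  }
  mu <- params$k_init * exp(params$b_rate * state$intervals_walked)
  if (params$noise_sd > 0) mu <- mu + rnorm(1L, 0, params$noise_sd)
  floor_bid(mu)
}

#' Advance a robo-bidder's state after an auction
#'
#' The walked-interval counter increments only when the robo-bidder won the
#' auction (and therefore walked); a losing robo-bidder's price curve is
#' frozen in place.
#'
#' @param state A [robo_state()].
#' @param won Did this robo-bidder win the auction?
#' @param bid The bid it submitted this auction (recorded for the
#'   literal-constant repeat mode); optional.
#' @return The updated `robo_state`.
#' @export
advance_robo_state <- function(state, won, bid = state$last_bid) {
  stopifnot(inherits(state, "robo_state"))
  state$last_bid <- bid
  state$last_t <- state$intervals_walked
  if (isTRUE(won)) {
    state$intervals_walked <- state$intervals_walked + 1L
  }
  state
}

#' Honest human bidding agent parameters
#'
#' A synthetic participant bidding honestly on an exponential internal
#' valuation: the private price to walk after `w` accumulated minutes of
#' walking is `k_true * exp(b_true * w)`. The fatigue clock is accumulated
#' *walking* time (two minutes per win), not session time: resting intervals
#' do not fatigue the agent. A `fixed-markup` strategy (honest value plus a
#' constant) is provided for robustness experiments only.
#'
#' @param k_true Initial private price in USD (>= 0.01).
#' @param b_true Exponential fatigue rate per walked minute (>= 0).
#' @param bid_noise_sd SD of Gaussian bid noise in USD (default 0, i.e.
#'   perfectly honest reporting).
#' @param strategy `"honest"` or `"fixed-markup"`.
#' @param markup Constant USD markup for the `fixed-markup` strategy.
#' @param cent_rounding Round bids to whole cents (the protocol's currency
#'   resolution). Disable for continuous-price simulation studies where
#'   exact parameter recovery is being validated numerically.
#' @return An object of class `human_agent`.
#' @export
human_agent <- function(k_true, b_true, bid_noise_sd = 0,
                        strategy = c("honest", "fixed-markup"), markup = 0,
                        cent_rounding = TRUE) {
  strategy <- match.arg(strategy)
  check_number(k_true, "k_true", min = 0.01)
  check_number(b_true, "b_true", min = 0)
  check_number(bid_noise_sd, "bid_noise_sd", min = 0)
  check_number(markup, "markup")
  structure(
    list(
      k_true = k_true, b_true = b_true, bid_noise_sd = bid_noise_sd,
      strategy = strategy, markup = markup,
      cent_rounding = isTRUE(cent_rounding)
    ),
    class = "human_agent"
  )
}

#' Human agent state
#'
#' @param minutes_walked Accumulated walking minutes (2 per auction won).
#' @param observed_clearing_prices Clearing prices disclosed so far; the
#'   session protocol reveals only the winning (second-lowest) bid after each
#'   interval, never the full bid vector.
#' @return An object of class `human_state`.
#' @export
human_state <- function(minutes_walked = 0, observed_clearing_prices = numeric()) {
  check_number(minutes_walked, "minutes_walked", min = 0)
  structure(
    list(
      minutes_walked = minutes_walked,
      observed_clearing_prices = observed_clearing_prices
    ),
    class = "human_state"
  )
}

#' Generate one honest human bid
#'
#' @param params A [human_agent()].
#' @param state A [human_state()].
#' @return A single bid in USD (cent-rounded, floored at $0.01).
#' @export
human_bid <- function(params, state) {
  stopifnot(inherits(params, "human_agent"), inherits(state, "human_state"))
  mu <- params$k_true * exp(params$b_true * state$minutes_walked)
  if (params$strategy == "fixed-markup") mu <- mu + params$markup
  if (params$bid_noise_sd > 0) mu <- mu + rnorm(1L, 0, params$bid_noise_sd)
  if (isTRUE(params$cent_rounding)) floor_bid(mu) else max(mu, 0.01)
}

#' Advance the human agent's state after an auction
#'
#' Winning means walking: the fatigue clock gains one interval's worth of
#' minutes. The disclosed clearing price is appended to the agent's observed
#' history either way.
#'
#' @param state A [human_state()].
#' @param won Did the human win (and therefore walk)?
#' @param clearing_price The disclosed winning (second-lowest) bid, USD.
#' @param interval_minutes Walking minutes bought by one won auction.
#' @return The updated `human_state`.
#' @export
advance_human_state <- function(state, won, clearing_price, interval_minutes = 2) {
  stopifnot(inherits(state, "human_state"))
  if (isTRUE(won)) {
    state$minutes_walked <- state$minutes_walked + interval_minutes
  }
  state$observed_clearing_prices <- c(state$observed_clearing_prices, clearing_price)
  state
}

#' Draw a default cohort of robo-bidder opponents
#'
#' Robo-bidder parameters are drawn from a documented uniform prior:
#' `k_init ~ U(0.40, 1.00)` USD and `b_rate ~ U(0.15, 0.30)` per walked
#' interval, with $0.01 bid noise. The prior is calibrated so that, against
#' the default honest-bidder prior, the median participant walks roughly half
#' of the session: win shares in a sequential second-price equilibrium scale
#' inversely with each agent's per-win log price growth, so the robo growth
#' per interval is set to roughly three times the human's.
#'
#' @param n Number of robo-bidders (default 3, one human vs three robos).
#' @param k_range,b_range Ranges of the uniform priors.
#' @param noise_sd Bid-noise SD passed to every robo-bidder.
#' @return A list of `n` [robo_bidder()] parameter sets.
#' @export
make_default_robo_cohort <- function(n = 3, k_range = c(0.40, 1.00),
                                     b_range = c(0.15, 0.30), noise_sd = 0.01) {
  if (!is_scalar_number(n) || n < 1) {
    abort_validation("`n` must be a single number >= 1")
  }
  n <- as.integer(n)
  ks <- runif(n, k_range[1], k_range[2])
  bs <- runif(n, b_range[1], b_range[2])
  purrr::map2(ks, bs, robo_bidder, noise_sd = noise_sd)
}
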