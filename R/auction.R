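#' Settle a sealed-bid second-price (Vickrey) auction
#'
#' In the *selling* (reverse) variant the lowest bid wins and the winner is
#' paid the second-lowest bid; in the *buying* (forward) variant the highest
#' bid wins and the winner pays the second-highest bid. The second-price rule
#' makes truthful bidding the dominant strategy in both directions, which is
#' what lets the auction elicit a bidder's private valuation.
#'
#' Ties for the best bid are broken uniformly at random; under a tie the
#' clearing price equals the tied value (the second element of the sorted bid
#' multiset). All comparisons are performed on integer cents, so amounts that
#' agree to the cent are exact ties.
#'
#' @param bids A data frame with columns `bidder_id` (unique within the
#'   auction) and `amount` (USD, at least $0.01).
#' @param variant `"selling"` (reverse) or `"buying"` (forward).
#' @return An object of class `auction_outcome`: a list with `winner_id`,
#'   `clearing_price` (USD), `variant`, `tie_broken`, and `sorted_bids`
#'   (bids sorted best-first).
#' @examples
#' bids <- tibble::tibble(bidder_id = c("H", "R1", "R2"), amount = c(1, 2, 3))
#' settle_reverse_vickrey(bids)
#' @export
settle_vickrey <- function(bids, variant = c("selling", "buying")) {
  variant <- match.arg(variant)
  if (!is.data.frame(bids) || !all(c("bidder_id", "amount") %in% names(bids))) {
    abort_validation("`bids` must be a data frame with columns `bidder_id` and `amount`")
  }
  ids <- as.character(bids$bidder_id)
  amt <- bids$amount
  if (length(ids) < 2L) {
    abort_protocol("a Vickrey auction needs at least 2 bids")
  }
  if (anyDuplicated(ids)) {
    abort_validation("`bidder_id` must be unique within one auction")
  }
  if (any(!is.finite(amt)) || any(amt < 0.01)) {
    abort_validation("all bid amounts must be finite and >= $0.01")
  }
  cents <- to_cents(amt)
  core <- settle_core(cents, variant)

  ord <- order(cents, decreasing = variant == "buying")
  structure(
    list(
      winner_id = ids[core$winner],
      clearing_price = from_cents(core$clearing),
      variant = variant,
      tie_broken = core$tie_broken,
      sorted_bids = tibble(bidder_id = ids[ord], amount = from_cents(cents[ord]))
    ),
    class = "auction_outcome"
  )
}

# Second-price settlement on integer cents: winner index, clearing price in
# cents, tie flag. Shared by the public settle functions and the session
# simulator's inner loop.
settle_core <- function(cents, variant) {
  best <- if (variant == "buying") max(cents) else min(cents)
  tied <- which(cents == best)
  tie_broken <- length(tied) > 1L
  winner <- if (tie_broken) tied[sample.int(length(tied), 1L)] else tied
  sorted <- sort(cents, decreasing = variant == "buying")
  list(winner = winner, clearing = sorted[2L], tie_broken = tie_broken)
}

#' @rdname settle_vickrey
#' @export
settle_reverse_vickrey <- function(bids) settle_vickrey(bids, "selling")

#' @rdname settle_vickrey
#' @export
settle_forward_vickrey <- function(bids) settle_vickrey(bids, "buying")

#' @export
print.auction_outcome <- function(x, ...) {
  cat(sprintf(
    "<auction_outcome> %s auction, %d bids\n  winner: %s at clearing price $%.2f%s\n",
    x$variant, nrow(x$sorted_bids), x$winner_id, x$clearing_price,
    if (x$tie_broken) " (tie broken at random)" else ""
  ))
  invisible(x)
}

#' @method tidy auction_outcome
#' @export
tidy.auction_outcome <- function(x, ...) {
  mutate(x$sorted_bids,
    won = .data$bidder_id == x$winner_id,
    clearing_price = x$clearing_price,
    variant = x$variant
  )
}
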