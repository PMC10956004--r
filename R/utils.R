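# Currency helpers. All settlement arithmetic runs on integer cents so that
# equality comparisons (ties, clearing prices) are exact; the user-facing
# surface stays in USD doubles.

to_cents <- function(usd) as.integer(round(usd * 100))

from_cents <- function(cents) cents / 100

#' Round an amount to whole cents
#'
#' @param usd Numeric vector of USD amounts.
#' @return Numeric vector rounded to cent resolution.
#' @keywords internal
round_to_cents <- function(usd) round(usd * 100) / 100

# Bids are floored at one cent: agents never submit zero or negative prices.
floor_bid <- function(usd) pmax(round_to_cents(usd), 0.01)

abort_validation <- function(msg) abort(msg, class = "ptw_validation_error")

abort_protocol <- function(msg) abort(msg, class = "ptw_protocol_error")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, min = -Inf) {
  if (!is_scalar_number(x) || x < min) {
    abort_validation(sprintf("`%s` must be a single finite number >= %s", name, format(min)))
  }
  invisible(x)
}
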