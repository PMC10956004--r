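Package: pricetowalk
Title: Economic Valuation of Wearable Assistance via Sequential Vickrey Auctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for eliciting and analysing the perceived economic value of
    wearable assistive devices (e.g. lower-limb exoskeletons) with sequential
    reverse Vickrey auctions in which a participant sells two-minute bouts of
    strenuous walking. Provides second-price auction settlement (selling and
    buying variants), exponential robo-bidder and honest-bidder agents, a full
    session simulator, price-to-walk curve fitting Y(t) = k*exp(b*c*t) with
    win-rate scaling, cumulative price and marginal-value (MV) statistics with
    baseline normalisation and dollars-per-hour conversions, cohort-level
    inference (SEM, one-sample t-tests, Cohen's d), test-retest reliability
    with minimum detectable change (MDC) and responder classification, a
    synthetic-cohort generator with known ground truth, bid-log CSV/YAML I/O,
    ggplot2 figures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
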