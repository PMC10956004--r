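# pricetowalk

Economic valuation of wearable assistive devices via sequential reverse
Vickrey auctions.

## What this package is for

Augmentative exoskeletons assist able-bodied wearers, but the field's
standard success metric — reduced metabolic rate — is poorly perceived by
the users themselves, and stated-preference instruments carry well-known
biases because nothing is at stake. This package implements an
incentive-compatible alternative for researchers studying wearable
assistance: the participant repeatedly **sells** 2-minute bouts of
strenuous walking in sealed-bid second-price (Vickrey) auctions against
computerized opponents, for real money. In the selling variant the lowest
ask wins but is paid the *second-lowest* ask, which makes truthfully asking
one's private valuation the dominant strategy; the resulting bid sequence
is the participant's *price-to-walk* curve.

The analysis chain:

1. **Curve fit.** Each session's bids are fit with a first-order
   exponential `Y(t) = k·exp(b·c·t)`, where `t` is session time and `c` is
   the participant's win rate — the scaling that converts session time into
   expected walking time, so `b` is a fatigue rate per *walked* minute.
2. **Cumulative price.** The fitted curve is integrated in closed form over
   a 0–30 min walking window: `(k/b)·(exp(30b) − 1)` USD.
3. **Marginal value (MV).** The difference of cumulative prices between a
   baseline condition (e.g. normal walking) and a device condition
   (powered or unpowered exoskeleton), expressed in USD or as a percent of
   the participant's own baseline — positive MV means the device made
   walking cheaper, i.e. added value.
4. **Cohort statistics.** One-sample t-tests and effect sizes on
   per-subject MVs; test–retest reliability from repeated baseline
   sessions, the minimum detectable change `MDC = z·√2·SD_intra`, and
   responder classification against the MDC threshold.

A synthetic-cohort generator with closed-form ground truth (honest
exponential bidders, win-gated exponential robo-bidders, configurable
condition effects) makes the entire pipeline testable end to end without
any external data.

## Worked example

```r
library(pricetowalk)

cohort <- simulate_cohort(reference_design_spec(seed = 1))  # 49 session logs
analysis <- analyze_cohort(cohort)
analysis
```

```
<cohort_analysis> 49 sessions, 16 subjects; window [0, 30] min
  mean fit R^2: 0.953
  assistance-alone: mean MV 34.9% (SD 47.4, SEM 15.0, n=10), t(9)=2.32, p=0.045, d=0.74
  exo-powered vs walking-no-exo: mean MV -1.7% (SD 17.4, SEM 4.3, n=16), t(15)=-0.38, p=0.708, d=-0.10
  exo-powered-off vs walking-no-exo: mean MV -39.6% (SD 40.8, SEM 12.9, n=10), t(9)=-3.07, p=0.013, d=-0.97
  reliability: intra-subject SD 3.68%, MDC 10.2% at 95% confidence
  responders (exo-powered vs walking-no-exo, threshold 10.2%): 3 positive, 5 negative, 8 indeterminate
```

Reading this: in this synthetic cohort the unpowered device imposed a
significant cost (mean MV −39.6% of each subject's baseline cumulative
price — wearing an unpowered device is like walking with added mass), the
assistance alone added significant value (+34.9%), and the two roughly
cancel in the net powered-device condition (−1.7%, not distinguishable from
zero). The MDC of 10.2% is the smallest MV a single subject could exhibit
that exceeds day-to-day measurement noise at 95% confidence; 8 of 16
subjects fall inside that indeterminate band.

Individual pieces compose with the pipe:

```r
log <- run_session(human_agent(k_true = 0.5, b_true = 0.04, bid_noise_sd = 0.05),
                   make_default_robo_cohort(3),
                   session_config(seed = 7))
fit <- fit_price_to_walk(log)
glance(fit)                       # k_hat, b_hat, c, R^2 as a tibble
cumulative_price(fit)             # USD over 0-30 min of walking
autoplot(fit)                     # bids (circles win, squares lose) + curve
mv_to_hourly(58.50, -31.8)        # percent MV -> $/h against a baseline rate
```

Bid logs round-trip through a fixed CSV schema (`write_bid_log()` /
`read_bid_log()`), with a YAML sidecar that re-simulates a session
bit-exactly. A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ptw.R", package = "pricetowalk"))')" \
  cohort --preset reference-design --seed 1 --out-dir cohort_out
```

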