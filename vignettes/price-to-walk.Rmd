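---
title: "Measuring the economic value of wearable assistance with sequential Vickrey auctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the economic value of wearable assistance with sequential Vickrey auctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pricetowalk)
library(dplyr)
```

## The measurement problem

Whether a wearable assistive device — a powered ankle exoskeleton, say —
actually helps its wearer is surprisingly hard to quantify. Physiological
metrics such as metabolic rate are objective but poorly perceived by users,
and stated-preference instruments (ratings, questionnaires) are vulnerable
to self-enhancement and social-desirability biases because nothing is at
stake. `pricetowalk` implements an *incentive-compatible* alternative: the
participant repeatedly **sells** bouts of strenuous walking in sealed-bid
reverse Vickrey auctions for real money, and the price they demand — their
*price to walk* — is read off their bids.

In a reverse (selling) Vickrey auction the lowest ask wins but is paid the
**second-lowest** ask. This second-price rule decouples the winner's payment
from their own bid, which makes truthfully asking one's private valuation a
dominant strategy: bidding above your true price risks losing a profitable
sale, bidding below risks selling at a loss, and neither can improve the
price you are actually paid. The package's `settle_reverse_vickrey()` (and
its buying twin `settle_forward_vickrey()`) implement this rule on integer
cents; the dominance property is verified in the test suite by exhaustive
payoff enumeration over a cent grid.

## The session protocol

One *session* is a series of sealed-bid auctions, each selling one 2-minute
walking bout:

* every interval, the participant and `n_robo` computerized opponents
  ("robo-bidders") submit sealed asks;
* the lowest ask wins; if the participant wins they walk the bout and are
  paid the clearing price (the second-lowest ask), otherwise they rest;
* only the clearing price is disclosed — never the full bid vector — so the
  participant cannot reverse-engineer the opponents;
* the session lasts a uniformly random 50–70 minutes (mean 60), so waiting
  out the opponents is not a viable strategy. With 2-minute bouts this
  yields 25–35 auctions per session.

`run_session()` simulates this protocol and returns a complete bid log (one
row per bidder per interval). Two conventions are worth stating because the
protocol itself does not force them: the auction count is
`floor(scheduled / interval)` — a bid buys a whole bout, so a partial
trailing interval is dropped — and the participant submits a bid in *every*
interval, including those following losses, because every auction requires a
sealed bid from every bidder.

### Bidding agents

Robo-bidders ask `k_init * exp(b_rate * t_k) + noise`, where `t_k` counts
the intervals **that robo-bidder has walked** (i.e. its own wins). A losing
robo-bidder's deterministic price is frozen; a winning one fatigues and
raises its ask. The Gaussian noise (SD $0.01 by default) exists to mask the
deterministic model from the human opponent. We interpret the $0.01 as a
standard deviation (it is stated as one); fresh noise is drawn every
auction even after losses, with `literal_constant = TRUE` available to
re-submit the exact previous number instead.

The synthetic honest participant asks `k_true * exp(b_true * w)`, where `w`
is **accumulated walking time** (2 minutes per win). This is a deliberate
choice: fatigue accrues from walking, not from sitting out rest intervals,
and it is exactly the clock that the win-rate scaling in the curve fit
(below) is designed to recover. Optional Gaussian bid noise models honest
but imprecise reporting; a `fixed-markup` strategy exists only for
robustness experiments. All bids are cent-rounded and floored at $0.01;
`cent_rounding = FALSE` switches to continuous prices for simulation
studies that validate exact parameter recovery, where the half-cent
quantization error would otherwise dominate.

## The price-to-walk curve

Bids rise as the participant fatigues, and the trend is well captured by a
first-order exponential. `fit_price_to_walk()` fits

$$Y(t) = k \, e^{b c t}$$

to **all** of a session's bids — winning and losing alike, both carry
valuation information — by least squares, with $t$ the session time of each
auction and $c$ the session *win rate*, fixed rather than fitted. Since the
participant walks only the intervals they win, $c\,t$ is the expected
walking time at session time $t$; $c$ therefore controls for how much of
the session each participant actually walked, and makes $b$ a fatigue rate
per *walked* minute, comparable across participants with different win
rates.

Numerically the problem is reduced to one dimension by profiling: for any
candidate rate, the optimal $k$ is the closed-form projection
$\sum y u / \sum u^2$ with $u = e^{bct}$, so a coarse grid over $b \in [0, 1]$
per minute (241 points) followed by golden-section refinement
(`stats::optimize`, tolerance $10^{-10}$) finds the global optimum; the
test suite checks the result against an independent brute-force
$(k, b)$-grid search to $10^{-6}$ in the objective. The rate is constrained
non-negative by default (bids invariably trend upward); `nonneg_rate =
FALSE` lifts this. Degenerate cases follow documented conventions:
all-constant bids give $b = 0$ with $R^2 = 1$ (zero residual against zero
total variance), and a session with no wins ($c = 0$) is an error, since
the model cannot separate $k$ from $b$ when the regressor collapses.
$R^2 = 1 - SS_{res}/SS_{tot}$ is reported as fit quality.

## Cumulative price and marginal value

The integral of a fitted curve over a fixed walking-time window — 0 to 30
minutes by default, roughly the time a participant actually walks in one
session — is the **cumulative price to walk** in USD:

$$\int_{t_1}^{t_2} k\,e^{b t}\,dt \;=\; \frac{k}{b}\left(e^{b t_2} - e^{b t_1}\right),$$

with the limit $k(t_2 - t_1)$ as $b \to 0$. Note the integrand uses the
per-walked-minute rate $b$, *not* the composite session-time rate $bc$:
the win-rate scaling exists precisely so that the fitted $b$ refers to
continuous walking, and the window is interpreted as 30 minutes of actual
walking in every condition. Integrating the session-time curve instead
would re-introduce the different walking shares that $c$ was introduced to
remove, and would make two sessions with identical fatigue but different
win rates appear to have different valuations. `cumulative_price()`
implements the closed form with `expm1()` (the naive `exp(x) - 1` loses
nine significant digits near $b \approx 10^{-9}$) and switches to the
analytic limit below $|b| < 10^{-12}$; agreement with adaptive quadrature
is maintained to $10^{-9}$ relative error across the whole rate range,
including a dense neighbourhood of zero.

The **marginal value** between two conditions is the difference of their
cumulative prices, baseline minus comparison:

$$MV = \int_{t_1}^{t_2} k_1 e^{b_1 t}\,dt - \int_{t_1}^{t_2} k_2 e^{b_2 t}\,dt.$$

A positive MV means the comparison condition is *cheaper* — the device (or
its assistance) added value. Because absolute valuations of time differ
enormously between people (socioeconomic status, athleticism, opportunity
cost), MV is normalised by the participant's own baseline cumulative price
and expressed in percent. `hourly_rate()` and `mv_to_hourly()` convert to
dollars per hour; for the default 30-minute window the chain
`mv_to_hourly(hourly_rate(base), mv_percent) == 2 * mv_usd` holds as an
algebraic identity and is asserted numerically in the tests.

For the three-condition design (baseline walking, powered device, unpowered
device) `compute_mvs()` also forms the *assistance-alone* contrast —
unpowered minus powered — which isolates the value of the assistance from
the cost of wearing the device's mass. Its percentage is still normalised
by the subject's baseline cumulative price, keeping all three percentages
on a common scale.

## Reliability: SEM, MDC and responders

Cohort inference is deliberately plain: a two-tailed one-sample t-test of
the per-subject MV percentages against zero per comparison
(`one_sample_t()`, delegating to `stats::t.test`), SEM $= SD/\sqrt{N}$, and
the uncorrected one-sample Cohen's $d = \bar{x}/SD$. Sample SDs use the
$n-1$ denominator throughout, as is standard for small human cohorts. No
multiple-testing correction is applied across the three planned
comparisons.

Test–retest reliability comes from participants who repeat the baseline
condition on different days. `repeatability()` expresses each repeater's SD
of cumulative prices as a percentage of their own mean and averages across
repeaters; the **minimum detectable change** is then

$$MDC = z_{1-\alpha/2} \cdot \sqrt{2} \cdot SD_{intra},$$

the smallest between-measurement change distinguishable from day-to-day
noise at the chosen confidence (the $\sqrt 2$ reflects that a change is a
difference of two noisy measurements; $z \sqrt 2 = 2.772$ at 95%).
`classify_responders()` labels each subject positive, negative or
indeterminate by strict comparison of their MV against $\pm$threshold,
defaulting to the computed MDC. `analyze_cohort()` chains all of the above.

## The synthetic cohort generator

`simulate_cohort()` generates complete studies with known ground truth, so
the whole pipeline can be validated without any external data. Its defaults
define the study conditions and are not tuning knobs:

* **Subject priors** $k \sim U(0.25, 0.75)$ USD,
  $b \sim U(0.02, 0.06)$ per walked minute: chosen so bids sit in the
  $0.10–$5.00 range with session means near $0.75–$1, the regime a
  strenuous-walking auction produces in practice.
* **Robo-bidder prior** $k \sim U(0.40, 1.00)$ USD,
  $b \sim U(0.15, 0.30)$ per walked interval. In a sequential second-price
  equilibrium agents rotate wins and win shares scale roughly inversely
  with per-win log price growth; setting the robo growth per interval to
  about three times the human's ($\approx 2 \times 0.04$ per 2-min win)
  makes the median honest participant walk about half the session, matching
  the intended protocol load. Simulation confirms a median walking share of
  0.53 under these defaults.
* **Condition effects** multiply the fatigue rate $b$ (difficulty is what
  the conditions change): 0.92 for the powered device and 1.375 for the
  unpowered device, which at the prior-mean $b = 0.04$ put the true MVs
  near $+6\%$ and $-32\%$ — the qualitative regime the instrument is meant
  to resolve. A per-subject log-normal jitter (SD 0.30) on the multiplier
  creates the wide between-subject spread of device responses; an
  additive-$k$ effect mode exists for robustness checks.
* **Bid noise** SD $0.05: large enough that fits are visibly imperfect
  (typical $R^2$ in the high 0.8s–0.9s) yet small enough that condition
  effects remain detectable — the operating point of a usable instrument.

`reference_design_spec()` bundles the reference design: 16 subjects in baseline
and powered conditions, ten of them also in the unpowered condition, and
four further subjects repeating baseline (three twice more, one once more)
— 42 condition sessions, 49 logs with repeats.

What the generator deliberately does **not** emulate: strategic or
adaptive human bidding (the protocol is designed to make honesty optimal,
so agents are honest by construction), boredom or opportunity-cost effects
of rest intervals, day-to-day parameter drift in repeaters (repeat
variability arises only from bid noise and auction stochasticity), and
learning effects across conditions. Passing tests therefore demonstrate
that the *estimator pipeline* is correct and calibrated under the stated
generative model — not that real participants bid honestly or
exponentially.

### What validation shows

Two properties anchor the pipeline validation. With noiseless continuous
prices and uncontested opponents (win rate 1, so walked time equals session
time), the fit recovers the generating $(k, b)$ to $10^{-6}$ and per-subject
MVs match the closed-form ground truth — the estimator is exact when its
model holds exactly. Under competitive opponents the walked-time clock only
approximates $c \times$ session time (wins cluster early while the
equilibrium forms), so individual MVs carry a few points of approximation
error; across replicate cohorts this error averages out, and the
cohort-mean MV is unbiased to well within 2 percentage points at bid noise
$0.05 (checked over 200 replicate cohorts of six subjects in the
acceptance suite — sizes chosen to make the Monte-Carlo error on the bias
estimate a fraction of the tolerance).

## Worked example

```{r example}
cohort <- simulate_cohort(reference_design_spec(seed = 1))
analysis <- analyze_cohort(cohort)
analysis
```

Per-subject marginal values and the fitted curves are plain tibbles and
ggplots:

```{r tables}
analysis$mvs |> count(comparison)
glance(analysis)
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(analysis$fits$fit[[1]])
```

## Known limitations

* MV extrapolates both fitted curves to a common 30-minute walking window;
  for low win rates this extrapolates beyond the walking actually observed,
  with no uncertainty band attached.
* Per-subject MV estimates are biased by a few percentage points when win
  patterns are strongly non-uniform in time; only cohort means are
  validated as unbiased.
* The exponential form is assumed, not selected; alternative response
  shapes (linear, logistic) are out of scope.
* Robo-bidder parameters are drawn from a calibrated prior, not estimated
  from pilot data; absolute cumulative prices in synthetic cohorts are
  therefore only regime-realistic, not distribution-matched.
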