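---
title: "Joint monitoring of accrual and UBR enrollment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint monitoring of accrual and UBR enrollment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubrmonitor)
```

## The monitoring problem

A trial plans to enroll `n` participants within a window `T`, often with
an additional goal for the combined rate of participants from
underrepresented-in-biomedical-research (UBR) categories — non-white,
Hispanic/Latino, rural, and similar NIH-designated disparity groups. At
an interim look the monitoring data are deliberately minimal, because
that is all a DSMB report contains: the number enrolled `m`, the elapsed
accrual time `t_m`, and one aggregated count per UBR category.
`ubrmonitor` turns that state into a joint predictive distribution of
the final sample size and the final combined UBR rate (rUBR), from which
credible intervals and probabilities of meeting targets follow.

## Accrual model

Waiting times between consecutive enrollments, `w_i = t_i - t_{i-1}`,
are modeled as i.i.d. exponential with mean `theta`. The conjugate prior
is inverse-gamma,

$$\theta \sim \mathrm{IG}(k, V), \qquad k = nP,\; V = TP .$$

We use the shape–scale convention: `IG(a, b)` has density proportional
to $\theta^{-(a+1)} e^{-b/\theta}$, so `1/theta ~ Gamma(shape a, rate b)`
and the mean is `b/(a - 1)` for `a > 1`. We state this explicitly
because inverse-gamma conventions differ between libraries and the
prior literature; every formula in the package assumes this one.

The prior is a pseudo-experiment: it is worth `nP` enrollments observed
over `TP` time-units, so its strength is governed by a single elicited
confidence `P` in `[0, 1]` (a 1–10 elicitation divided by 10; values of
0.1–0.5 are typical in practice). `P = 0` is the flat-prior limit; the
posterior then depends only on the data. The same `P` deliberately
scales the accrual prior and every category prior: one knob, one
interpretation ("how confident am I in the design assumptions?"). A
per-category confidence would be easy to add but is not part of this
version. `P` is treated as fixed for the whole trial; re-eliciting it at
later looks would change the meaning of the prior pseudo-experiment
mid-stream, so if users want that they should rebuild the design object
and treat the analyses as separate.

After `m` enrollments at elapsed time `t_m` the posterior is
`IG(A, B)` with `A = k + m`, `B = V + t_m`. Monitoring looks strictly
between enrollments do not contribute the censored, in-progress waiting
time: the likelihood stops at the `m`-th enrollment. That discards a
small amount of information (at most one partially observed waiting
time) in exchange for needing only what aggregated reports contain.
With `P = 0` and `m = 0` there is no information at all; the posterior
is improper and the package raises an error of class
`ubr_improper_posterior` rather than returning something arbitrary.

### Predictive sample size

For each of `s` draws, `theta_j ~ IG(A, B)` and the predicted final
sample size is `m` plus the number of further exponential waiting times
whose cumulative sum fits in the remaining budget `L = max(0, T - t_m)`
(a trial past its window has `L = 0` and the prediction collapses to the
observed state). By the renewal/Poisson-process equivalence that count
is `Poisson(L / theta_j)`, which is what the default sampler draws;
`method = "sequential"` in `draw_sample_sizes()` counts the waiting
times explicitly, and the test suite verifies the two routes agree in
distribution. Marginally over the posterior the additional count is
negative binomial with size `A` and success probability `B / (B + L)`
(`dpredcount()`, `predictive_count_pmf()`); the Monte-Carlo sampler is
tested against this closed form, and the closed form is never used *as*
the sampler — the joint prediction needs the per-draw pairing below.

Predicted draws are not capped at the design target `n`: a trial ahead
of schedule is predicted to overshoot, which is exactly what a monitor
wants to see.

## UBR model

Membership of subject `i` in category `u` is Bernoulli with probability
`p^u`; the aggregated count after `m` subjects is
`S_m^u ~ Binomial(m, p^u)`. The conjugate prior

$$p^u \sim \mathrm{Beta}(\alpha^u, \beta^u), \qquad
  \alpha^u = p_0^u nP,\; \beta^u = (1 - p_0^u) nP$$

is again a pseudo-experiment: `nP` subjects at the prior expected rate
`p_0^u`, which an investigator naturally sets to the category's target
rate. The posterior is
`Beta(alpha^u + S_m^u, beta^u + m - S_m^u)`.

A boundary elicitation `p_0 = 0` or `1` with `P > 0` puts all prior
mass on one side and the prior is improper for sampling. The package
raises rather than silently regularizing: adding a pseudo-count behind
the user's back would change the prior they elicited. The error message
suggests nudging `p_0` off the boundary.

For each accrual draw `j` a fresh rate `p_j^u` is drawn from the
posterior and the future count from
`Binomial(n_j^p - m, p_j^u)` — one rate draw per accrual draw, so that
rate uncertainty, not just binomial sampling noise, propagates into
every prediction. With the remaining size held fixed the future count is
exactly beta-binomial (`dbetabinom()`, `betabinom_pmf()`), the second
closed-form oracle the sampler is tested against.

## The combined rUBR

Per draw,

$$\mathrm{rUBR}_j^p = \sum_u \frac{S^u_{n_j^p}}{n_j^p}, \qquad
  S^u_{n_j^p} = S^u_m + S^u_{n_j^p - m},$$

and at trial completion
$\mathrm{rUBR}_f = \sum_u n_f^u / n_f$. Categories are modeled as
independent binomials because aggregated counts cannot express overlap.
The additive formula therefore double-counts subjects who belong to
several categories; with extensive overlap the combined rate is
overestimated and individual draws can exceed 1. The package reports
such draws with a warning and never clamps them — clamping would hide
the aggregation bias instead of surfacing it. The synthetic generator's
forced-overlap mode exists purely to demonstrate this effect in tests.
An overlap-aware model on unaggregated subject-level flags would be the
remedy, but it requires data that interim reports typically do not
provide and is out of scope here.

## Summaries, targets, reports

* **Point estimates**: the predictive sample-size distribution is
  discrete and can be skewed, so the default point estimate is the
  median, with the mean reported alongside.
* **Intervals**: equal-tailed 95% credible intervals (2.5th and 97.5th
  percentiles of the draws), the conventional reading of "95% CI" in
  monitoring tables.
* **Meeting probabilities**: the proportion of draws *at or above* the
  target. Equality counts as meeting; the convention is arbitrary at
  ties but fixed and documented, and with the window exhausted the
  probabilities become exact 0/1 indicators of the observed state.
* **Display**: rates are shown to 3 decimals and sample sizes as
  integers; stored values keep full precision.
* **Reports**: `write_report()` emits a schema-versioned JSON document
  (settings, then one block per look with estimates, intervals and
  probabilities; raw draws only behind a flag). Reports contain no
  timestamp so that identical seeds give byte-identical documents.

## Reproducibility

Every sampling function takes a `seed`. One generator is seeded per
prediction call and the draw order is fixed (accrual rates, accrual
counts, then each category's rates and counts in design order), so runs
with the same seed are bit-reproducible. `summarize_interims()` derives
per-look seeds as `seed + look - 1`.

## The synthetic-trial generator

`generate_trial()` produces enrollment logs with exactly the generative
structure the models assume: i.i.d. exponential inter-arrivals with mean
`theta`, stopping at whichever of the horizon or the subject cap binds
first (as real trials end at target or time), and independent Bernoulli
category flags. `adore_like_trial()` packages a configuration emulating
the published *shape* of a large multi-year obstetric trial — target
1355 over 48 months at `P = 0.3`, a true accrual pace giving a final
enrollment near 1100, non-white and Hispanic rates near 0.27 and 0.22,
and ten quarterly looks starting at the 300th enrollment; the prior
rates in its design (0.30 and 0.20, combined target 0.5) are plausible
investigator targets of the same magnitude. No subject-level data from
any real trial is involved.

What passing tests on these fixtures do **not** show: real accrual is
rarely time-homogeneous (ramp-up, seasonality, site activation), real
category flags can be correlated with calendar time and with each
other, and real reports arrive with lag. The generator shares the
models' assumptions by construction, so the simulation studies validate
the *inference machinery* (conjugate updates, samplers, intervals), not
the adequacy of the exponential/Bernoulli assumptions for any given
trial.

## Simulation studies in the test suite

The suite's statistical checks use sizes chosen to make Monte-Carlo
noise negligible relative to the tolerances while keeping the default
run fast: goodness-of-fit comparisons of the samplers against their
closed forms use 50,000 draws at the 0.001 level; parameter recovery
uses 100 replicate trials of 2,000 subjects with flat priors (mean
relative error below 5%); and interval calibration simulates 500 trials
from the prior predictive of a 200-subject design and checks that the
nominal 95% predictive intervals for final sample size and final rUBR
cover the realized values to within ±3%.

## Known limitations

* Aggregated counts: overlap between categories inflates the combined
  rUBR (see above).
* A single constant accrual rate; no multi-center or time-varying
  extensions (the Poisson-gamma multi-center literature covers that
  ground).
* A constant confidence `P`; accelerated or hedging prior-confidence
  schemes are not implemented.
* Monitoring between enrollments ignores the censored in-progress
  waiting time (small information loss, matching what aggregated
  reports contain).
* Decision rules (stopping, recruitment redirection) are out of scope:
  the package informs those decisions, it does not make them.
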