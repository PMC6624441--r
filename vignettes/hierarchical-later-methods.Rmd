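---
title: "Hierarchical Bayesian LATER models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian LATER models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The LATER (Linear Approach to Threshold with Ergodic Rate) model treats a
reaction time as the first-passage time of a linearly rising decision
signal. On trial $i$ for person $p$ the signal climbs at a rate drawn
fresh from a Gaussian,

$$z_{p,i} \sim \mathcal{N}(\nu_p,\, 1),$$

until it reaches the person's response threshold $\theta_p$. The
*accretion rate* $\nu_p$ measures speed of information accumulation; the
*caution* $\theta_p$ measures how much evidence the person demands before
responding. Trial-to-trial variability in latency is then entirely
attributable to the random rise rate, which reproduces the right-skewed
shape of empirical latency distributions and the straight-line reciprobit
signature.

**Two readings of the latency distribution.** The first-passage
construction $y = \theta / z$ implies that the *reciprocal* latency is
Gaussian — the classic recinormal reading:
$1/y \sim \mathcal{N}(\nu/\theta,\, 1/\theta^2)$. A closely related
reading takes the latency itself to be Gaussian,
$y \sim \mathcal{N}(\nu/\theta,\, 1/\theta^2)$, generatively
$y = z/\theta$. The two differ only by the reciprocal transform, but they
are not the same distribution, and applied work in this area has used
both. This package implements both as first-class likelihood `form`s:

* `form = "direct"` (default): $y \sim \mathcal{N}(\nu/\theta, 1/\theta^2)$.
  This is the form consistent with a worked example we treat as canonical
  for the parameter scales: accretion 1 against caution 4 gives a mean
  latency of $1/4$ s (250 ms), and so does accretion 1.5 against caution
  6 — with typical estimate ranges $\nu \in [0.7, 1.6]$,
  $\theta \in [2, 6]$ for sub-second go-trial latencies.
* `form = "reciprocal"`: the recinormal reading, with the
  change-of-variables Jacobian $1/y^2$ included in the density.

Every likelihood computation in the package (fitting, simulation,
posterior prediction) honors the chosen form; a test verifies the exact
change-of-variables identity between the two.

**Hierarchy.** Person parameters receive group-level regressions on a
covariate vector $x_p$ (leading intercept; we use age, age of first use,
nicotine-dependence score, and cigarettes per day in the bundled study
emulation):

$$\nu_p = x_p \beta_\nu + \varepsilon_{p,\nu}, \qquad
  \theta_p = x_p \beta_\theta + \varepsilon_{p,\theta},$$

with residual scales $\sigma_\nu, \sigma_\theta$ quantifying unexplained
individual differences. By default the two residuals are independent; a
bivariate-normal option (`correlated_effects = TRUE`) adds a correlation
$\rho$ under a uniform prior, since it is substantively plausible that
fast accumulators are also less cautious. It is off by default because
with the typical number of participants ($\sim$17) $\rho$ is weakly
identified and the independent-residual model is the more parsimonious
default.

**Condition effects.** The two-session (smoke-as-usual vs. abstinent) by
two-trial-type (neutral vs. reward) design is dummy coded against the
smoke-as-usual/neutral baseline, giving three indicator columns ordered
as (neutral–abstinent, reward–smoke-as-usual, reward–abstinent). Each
non-baseline cell shifts both parameters additively:

$$\nu_n = \nu_p + g_n \delta_\nu, \qquad \theta_n = \theta_p + g_n \delta_\theta.$$

All person effects, regression weights, residual scales and condition
deviations are estimated simultaneously in one joint posterior; the
trial-wise rate $z$ is marginalized analytically and never sampled.

## Priors and numerical policies

Weakly informative defaults, all overridable through `later_prior()`:
$\mathcal{N}(0, 10^2)$ on every $\beta$ and $\delta$ component and
half-$\mathcal{N}(0, 5^2)$ on $\sigma_\nu, \sigma_\theta$. On the
parameter scales involved (order 1 for accretion, order 4 for caution,
order 0.1 for deviations) these are diffuse, and the number of trials per
person (hundreds) makes the data term dominate. A `flat` switch removes
the prior terms entirely for closed-form validation work.

Because the condition deviations act additively, a composed caution
$\theta_n = \theta_p + g\delta_\theta$ can in principle go non-positive.
We keep the additive parameterization and assign such parameter regions
log-density $-\infty$ (soft rejection inside the sampler) rather than
re-parameterizing to enforce positivity, preserving the interpretation of
$\delta$ as a plain difference. Under the direct form the same policy
applies to a non-positive composed mean latency ($\nu_n \le 0$). The
`positivity = "error"` policy turns the rejection into an exception for
debugging.

Covariates are centered and scaled to unit sample SD before fitting;
coefficients are reported on the standardized scale (with
`destandardize_beta()` for back-transformation). This is done for sampler
geometry and cross-covariate comparability; with covariates on wildly
different raw scales (years vs. questionnaire scores) the joint Gaussian
updates would otherwise be badly conditioned.

## Sampling

`later_fit()` runs a Metropolis-within-Gibbs sampler whose stationary
distribution is exactly `joint_log_posterior()`. Two structural facts
make this efficient:

1. The Gaussian data term is quadratic in the accretion-side parameters.
   Collapsed onto per person-by-cell sufficient statistics
   $(n, \sum w, \sum w^2)$ — with $w = y$ or $1/y$ depending on the form —
   the full conditional of the entire accretion block
   $(\nu_1..\nu_P,\ \delta_\nu,\ \beta_\nu)$ given the caution side is
   multivariate normal. The sampler draws that whole block *jointly and
   exactly* each iteration (Cholesky of an analytically assembled
   precision matrix), which removes the person-effect/condition-deviation
   trade-off that cripples coordinate-wise updates. The direct-form
   positivity constraint is enforced by rejection inside the block draw;
   away from degenerate data it essentially never fires.
2. The caution side ($\theta_p$, $\delta_\theta$, $\sigma$'s, $\rho$) is
   not conjugate (the data term carries $n \log \theta_n$). It uses
   adaptive random-walk Metropolis: person thresholds are proposed as a
   vector (persons are conditionally independent), deviations and scales
   as scalars, with Robbins–Monro adaptation of the proposal scales
   toward 0.44 acceptance *during burn-in only*, so the retained draws
   come from a fixed-kernel chain with the exact target. These updates
   are the mixing bottleneck and run twice per iteration. $\beta_\theta$
   is conjugate given the thresholds and is Gibbs-updated.

Because the likelihood enters only through sufficient statistics, the
per-iteration cost is independent of the number of trials — a full
default fit (6 chains × 2,000 iterations) takes on the order of ten
seconds regardless of whether a person contributed 75 or 750 trials.

**Parameterization.** We sample the person effects on the centered scale
(the effects themselves, not standardized offsets). With hundreds of
trials per person the effects are data-dominated, which is precisely the
regime where centered parameterization has the better posterior geometry
— and it is what makes the joint accretion-block conditional Gaussian.

**Initialization.** Chains start from per-person method-of-moments
estimates ($\theta \approx 1/\mathrm{sd}(w)$,
$\nu \approx \mathrm{mean}(w)/\mathrm{sd}(w)$) with seed-controlled
multiplicative jitter, deviations near zero, and scales from the spread
of the moment estimates. Starting instead from prior means would place
chains at $\nu \approx 0, \theta \approx 0$, inside the excluded
($-\infty$) region. All randomness — initialization and proposals — flows
from the single sampler seed; identical seeds reproduce draws bitwise.

**Convergence.** The split-chain Gelman–Rubin statistic (classic, not
rank-normalized) is computed for every sampled parameter; the summary
flags a fit at the conventional criterion $\hat R \ge 1.1$, and the
command-line `fit` run exits non-zero in that case. Defaults follow the
published settings for this model class: 6 chains × 2,000 iterations,
first 1,000 discarded — we read "2,000 iterations" as including the
burn-in, i.e. 1,000 retained per chain. Small studies (a handful of
persons) identify $\sigma_\nu, \sigma_\theta$ weakly and need longer
chains; the group-level scales are the slowest-mixing parameters there.

## Posterior predictive checks

`later_ppc()` regenerates `n_rep` (default 100) datasets with exactly the
observed design shape (same persons, cells and trial counts), each from
one posterior draw of all person effects and deviations. Draws are taken
*equally spaced* across the pooled retained draws rather than at random,
so the parameter draws are reproducible by construction and the seed
governs only trial-level noise; with 6,000 pooled draws and 100
replicates the spacing (60) exceeds the chains' autocorrelation length,
so the thinned and random schemes are practically equivalent. Summary
statistics (mean, SD, deciles/quartiles) are computed per replicate and
compared with the observed values via central 95% interval flags;
`ppc_overlay()` exports the observed histogram plus per-replicate kernel
densities (Gaussian kernel, Silverman's rule-of-thumb bandwidth) on a
common latency grid, at whole-dataset or single-person level, with a base
`plot()` method that overlays them.

## The study emulator

`simulate_study()` generates the full synthetic analogue of the
two-session incentivized Go/No-Go study the model was built for: 17
persons; per session 10 runs × 100 trials of which 75% are frequent-go
(the only trials modeled), half the runs rewarded — hence 750 modeled
trials per person per session, 25,500 in total; latencies observable in a
150–800 ms response window; covariates drawn as Gaussians rescaled to hit
the published sample moments *exactly* (age 31.06/13.82, age of first use
19.63/5.34, FTND 2.61/2.35, cigarettes per day centered at 11.08 — the
published table gives no usable SD for the last, so we chose 5.5 as
realistic for daily smokers averaging ~11). The generating truth
defaults: intercepts $\beta_{\nu,0} = 1.15$, $\beta_{\theta,0} = 4$
(centers of the reported estimate ranges), residual scales
$\sigma_\nu = 0.2$, $\sigma_\theta = 0.9$ (spreading 17 persons over
roughly those ranges), zero covariate slopes (no predictor explained
individual differences in the study), and condition deviations at the
published posterior means.

**What the emulator does not reproduce.** Real latency distributions are
not exactly (reci)normal; real covariates are not Gaussian (a
moment-matched draw can produce, say, a negative dependence score); and
real data contain no record of the latencies the window clipped. Passing
recovery tests on emulated data therefore validate the *implementation*
(that the sampler targets the stated posterior and recovers known truth),
not the model's adequacy for any particular dataset — that is what the
posterior predictive checks are for.

**The window and the likelihood.** The likelihood does not model the
150–800 ms observation window, mirroring the model as published. At the
default truth the generative Gaussian places roughly a third of its mass
outside the window (mean ≈ 290 ms, SD ≈ 250 ms at baseline), so windowed
simulation redraws a substantial fraction of trials — the redraw count is
recorded and tested against the exact normal-mass oracle — and fitting
windowed data with the unwindowed likelihood inherits a truncation bias
in the condition deviations. For this reason windowing is optional:
`window = TRUE` (default) emulates realistic recorded data, while
`window = FALSE` yields raw generative draws (including, under the direct
form, a small mass of non-positive latencies, which
`prepare_later_data(rt_min = NULL)` will pass through) and is the setting
used for exactness checks — moment tests, parameter recovery, predictive
calibration — where the fitted likelihood must match the generative
process exactly.

## Validation performed by the test suite

The suite (and nothing outside it) computes: exact worked-example
latencies and design arithmetic; term-by-term and change-of-variables
oracles for the likelihood; quadrature normalization; a closed-form
conjugate check of the sampler in a reduced model (caution pinned,
hierarchy switched off via fixed scales) at three Monte-Carlo standard
errors; recovery of the six condition deviations within three posterior
SDs on a 15-person × 300-trials-per-session study plus CrI coverage over
five scaled-down replications (10 persons × 150 trials per session);
split-$\hat R < 1.1$ for all parameters on the full 17 × 750 emulated
study at the default sampler settings; and predictive calibration of the
replicate-mean interval. Problem sizes were chosen as the smallest at
which each property is sharply testable.

## Known limitations

* No treatment of the no-go/inhibition side of the task, infrequent-go
  trials, lapses/contaminants, or an early express-response population.
* The window truncation is simulated but not modeled in the likelihood
  (see above); estimates from heavily windowed data are biased toward
  the window's interior.
* Random-walk updates make the group-level scales slow to mix when there
  are very few persons; watch $\hat R$ for $\sigma_\nu, \sigma_\theta$.
* The correlation option reports $\rho$ under a uniform prior; with
  ~17 persons its posterior is wide and prior-sensitive.
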