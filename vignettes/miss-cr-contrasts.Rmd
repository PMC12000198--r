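---
title: "Why miss/correct-rejection contrasts do not equate true strength"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why miss/correct-rejection contrasts do not equate true strength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misscr)
```

## The problem

A recurring design in unconscious-memory and unconscious-perception
research selects the trials on which a participant reports *no* awareness —
old items judged "new" (misses) and new items correctly judged "new"
(correct rejections, CRs) — and treats them as matched in conscious
strength, so that any residual difference on another measure is attributed
to unconscious processing. `misscr` implements the two statistical
mechanisms that break this logic, and a synthetic experiment in which a
single-latent-variable model with *no* unconscious component reproduces the
"unconscious memory" signature.

## Model 1: classical test theory and Kelley's Paradox

Observed scores decompose as $X_i = T_i + E_i$ with
$T_i \sim N(\mu_g, \sigma_T^2)$ per group and
$E_i \sim N(0, \sigma_E^2)$ independent of $T$. Reliability is
$\rho = \sigma_T^2 / (\sigma_T^2 + \sigma_E^2)$. Conditioning on the
*observed* score falling in a window $W$ (closed on finite ends; both
bounded and half-infinite windows are supported),

$$E[T \mid X \in W] \;=\; \mu_g + \rho\,\bigl(E[X \mid X \in W] - \mu_g\bigr),$$

because $(T, X)$ is bivariate normal with $\mathrm{cor}^2 = \rho$. Two
groups selected into the *same* window therefore keep distinct true means
whenever $\rho < 1$ — Kelley's Paradox. `conditional_true_mean()` is this
closed form; `kelley_simulation()` is its Monte-Carlo twin, and the test
suite holds the two against each other across a parameter grid at four
Monte-Carlo standard errors.

```{r kelley}
kelley_simulation(ctt_population(40, 10, 10, "disadvantaged"),
                  ctt_population(60, 10, 10, "advantaged"),
                  n = 20000, window = c(48, 52), seed = 1)
```

`expected_true_given_observed()` gives the point-conditional version
$E[T \mid X = x]$; `estimate_true_at_observed()` offers the two natural
sample estimators of it (a local mean around $x$, default half-width 0.5
score units, and the within-group least-squares line evaluated at $x$).
Single simulated datasets of 50,000 per group scatter around the analytic
values with a local-mean SE of roughly 0.3 score units, which is why
reference values quoted from any one run differ from the closed form in the
first decimal.

## Model 2: truncated strengths and the miss–CR gap

Recognition strengths are Gaussian: new items $N(0, 1)$ by convention, old
items $N(\mu_{old}, \sigma_{old}^2)$ (equal variance when
$\sigma_{old} = 1$; empirical ROC fits typically give
$\sigma_{old} \approx 1.3$). Observed strength adds independent Gaussian
measurement noise with SD $\sigma_E$. An item is called "new" when its
observed strength falls below the decision criterion $C$, expressed
relative to the new-item mean. The expected *true* strength of items
observed in a window is the same conditional-regression identity as above,
with the truncated-normal mean of the observed distribution inside:

$$E[T \mid X \in W] = \mu +
  \frac{\sigma_T^2}{\sigma_T^2 + \sigma_E^2}\,\bigl(m_X(W) - \mu\bigr).$$

`miss_cr_gap()` applies this to both distributions below $C$ and returns
$T_M - T_{CR}$. Two regimes matter:

* **With error** ($\sigma_E > 0$) the gap grows as error grows — the
  regression-to-the-mean channel. On the standard grid
  ($\mu_{old} \in \{0.5, 1, 1.5\}$, $\sigma_{old} \in \{1, 1.3\}$,
  $C \in \{-1, 0\}$) the rise is monotone except in the unequal-variance,
  low-mean cell ($\mu_{old} = 0.5,\ \sigma_{old} = 1.3,\ C = -1$), where
  the gap dips slightly before climbing through zero; the qualitative
  amplification claim still holds there as eventual behaviour, and the
  tests encode exactly that.
* **Without error** the gap is still nonzero: within any window the
  higher-mean distribution is the more negatively skewed
  (`truncated_skewness()`, closed-form moments cross-checked against
  adaptive quadrature to 1e-6), so under equal variance the gap is
  positive for *every* $d' > 0$ and every finite criterion. It tends to 0
  as the window shrinks or moves into the far lower tail, and to $d'$ as
  the criterion becomes extremely conservative (large $C$: the window then
  contains both whole distributions). Under unequal variance with a low
  old-item mean the zero-error gap can be negative or zero.

```{r gap}
miss_cr_gap(sdt_params(mu_old = 1), criterion = 0)
```

Numerical choices: truncated-normal means are computed from the Mills-ratio
form with the normalising mass assembled on the log scale
(`pnorm(log.p = TRUE)` plus a log-space subtraction), so windows with mass
down to ~1e-300 — e.g. the advantaged group below 30, or criteria many SDs
out — are handled without catastrophic cancellation; windows below that
mass raise a degenerate-selection error rather than returning noise.
Boundary ties sit below the criterion (they have probability zero under
continuous noise).

## The synthetic experiment

The generator emulates a two-stage recognition experiment: 75 participants;
per participant 60 studied, 60 new and 20 truly-new words drawn from a
synthetic 180-word pool; a living/nonliving study task; a 4-point
confidence rating task over the 120 old+new words; and a 60-trial 2AFC
stage built by the rating-matched pairing algorithm (maximum equal-rating
pairs, leftover words paired as "unequal", then 20 new members replaced by
truly-new words — unequal pairs first, then equal pairs rated 4, 3, and so
on). Defaults (all overridable in `experiment_config()`):

* `mu_old = 2.6`, `sd_old = 1`, `sd_error = 0.8` — the observed-strength
  separation is then $2.6/\sqrt{1+0.8^2} \approx 2.0$ new-item SDs, a
  typical verbal-recognition d′;
* `criteria = c(0.03, 0.75, 1.20) * sqrt(1 + 0.8^2)` — cutpoints that sit
  at 0.03/0.75/1.20 on the normalised observed axis;
* `study_accuracy = 0.95` — the level an attentive participant shows on
  clearly classifiable words;
* `retest_error_sd = 1.4` — fresh observation noise at the 2AFC stage,
  chosen once so that overall 2AFC accuracy lands in the mid-80% range
  while rating-1 pairs stay in the mid-60s;
* `sd_mu_participant = 0.75` — a participant-level shift of the old-item
  mean. Without it every participant is exchangeable and the
  between-participant split-half reliability of the recognition measure is
  0 by construction; 0.75 puts the Spearman–Brown-corrected reliability
  near 0.78, matching what adequate recognition confidence measures
  achieve in practice.

The generator is deliberately ignorant of the miss/CR vocabulary: ratings
come from cutting noisy strengths, 2AFC choices from comparing fresh noisy
observations of the same true strengths (`keep_latent = TRUE` exposes the
latents for model checking). Above-chance accuracy on rating-1 pairs is
therefore an *emergent* consequence of truncation plus regression to the
mean — the mechanism under study, not an injected effect.

Two emergent subtleties the pairing algorithm itself produces, worth
knowing before interpreting pipeline output:

* truly-new pairs inherit *high-rated* old words (the replacement order
  prefers unequal pairs, then rating-4 pairs), so truly-new accuracy
  exceeds chance even when `mu_old = 0`. The truly-new exclusion filter
  thus passes inattentive-but-memoryless participants at above the naive
  binomial rate;
* because pairs condition on ratings, closed forms that assume random
  pairing (e.g. overall accuracy $\Phi(d'/\sqrt{2})$ with noise-free
  choice) do not apply; with zero noise equal-rated pairs are exactly at
  chance.

What the generator does *not* emulate: real lexical norms (the word pool is
synthetic), response times, distractor-task behaviour, criterion drift,
non-Gaussian strengths, or item-level difficulty effects. Passing tests
therefore show the pipeline's statistical machinery is correct and that the
artifact mechanisms suffice to produce the signature — not that any
particular real dataset is artifact-only.

## The analysis pipeline

`analyze_experiment()` chains the stages; each is exported on its own.

* **Exclusions** (`apply_exclusions()`): drop participants below 85%
  study accuracy computed on clearly living (> 600) / clearly nonliving
  (< 200) words only, and below 60% on the 20 truly-new 2AFC pairs (both
  strict `<`, so exactly 60% passes); participants with fewer than 3
  rating-1 equal pairs stay in the sample but sit out the critical test.
  The filters are idempotent and order-independent.
* **d′** (`dprime_binary()`): ratings 3–4 count as "old"; degenerate 0/1
  rates get a log-linear correction (add 0.5 to the cell, 1 to the
  denominator) — applied only to the affected participant and flagged.
* **ML rating model** (`fit_criteria_mle()`): equal-variance Gaussian
  multinomial likelihood over the pooled 4-category counts, BFGS at
  relative tolerance 1e-8 on an unconstrained parameterisation
  (log-increments keep criteria ordered), method-of-moments start plus
  jittered multistarts; empty categories are reported, not patched.
* **2AFC tests** (`afc_tests()`): one-sample t against 0.5 with
  $d_z$; both one- and two-sided p-values are emitted and the two-sided
  one is the default read-out, since directional and non-directional
  conventions are both common here.
* **Split-half reliability** (`split_half_reliability()`): 5,000 random
  splits by default, stratified 30/30 within old and new serial positions
  so the same split applies to every participant; half-score = mean
  rating(old) − mean rating(new), chosen over per-half d′ for stability at
  30 items per half; Pearson r across participants, Spearman–Brown
  step-up, averaged over splits (zero-variance halves skipped and
  counted).
* **GLMM** (`fit_random_intercept_logistic()`): on equal-rating pairs
  only, `correct ~ rating + (1 | participant)`, binomial with Laplace
  approximation via `lme4::glmer`; rating 1 is the baseline so the
  intercept is the logit accuracy of "sure new" pairs. A binomial-Laplace
  fit is the only estimation route that matches the stated model for a
  binary outcome.
* **Power** (`power_n_one_sample_t()`): smallest n whose noncentral-t
  power reaches the target; `d_z = 0.3` at one-tailed α = .05 and power
  .80 gives n = 71.

```{r pipeline}
trials <- simulate_experiment(experiment_config(n_participants = 20), seed = 7)
report <- analyze_experiment(trials, n_splits = 200, seed = 1, glmm = FALSE)
glance(report)
```

## Design decisions on genuinely open points

* The point-conditional estimates at an observed score of 50 can be read
  off a finite simulation either by local averaging near 50 or by a fitted
  within-group regression line; both are provided
  (`estimate_true_at_observed()`), the analytic regression value is the
  exported ground truth, and no claim is made about which a given
  reference analysis used.
* Every stochastic operation takes an explicit seed and leaves the global
  RNG untouched (`withr::with_seed`); `simulate_experiment()` splits its
  master seed into per-participant sub-seeds by drawing them from the
  seeded stream, so any participant's data is reproducible from the master
  seed alone.
* Equal-rating matching within a rating category is random (seeded) — any
  maximum matching is equally consistent with "matched whenever possible".
* The 2AFC coin-flip tie-break only matters in the exactly-noise-free
  configuration; under continuous noise ties have probability zero.
* Reported p-values: both tails are computed; the two-sided value is the
  default.
* No multiple-testing correction is applied anywhere in the pipeline.

## Problem sizes used by the test suite

The suite verifies the simulation/closed-form agreement at 50,000 per group
(with 100-replication 99% bands for single-run reference values), the
Monte-Carlo oracle for expected true strength at $10^6$ draws over a
$3^4$ grid, null calibration of the critical test over 300 replications of
a 30-participant experiment, and parameter recovery of the ML rating model
from a 400-participant run. These sizes make the checks sharp while keeping
the whole suite in the minutes range on a single core.

## Known limitations

* Gaussian strengths and additive Gaussian noise throughout; uniform or
  discrete-state (high-threshold) alternatives change the conclusions and
  are out of scope.
* The equal-variance ML rating model is misspecified if the generating
  old-item variance differs from 1 (deliberately so — it mirrors common
  practice).
* Reliability of the synthetic experiment is governed by one heterogeneity
  parameter; real individual differences are richer.
* The pipeline assumes the trial-table schema documented in
  `simulate_experiment()`; mapping real exports onto it (column renames)
  is the caller's responsibility.
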