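---
title: "Hierarchical psychometric models and historical borrowing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical psychometric models and historical borrowing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the hierarchical probit model and its variants, the power prior, the sampler,
the comparison metrics, the synthetic-data generator, and the numerical and
design choices made where more than one convention was defensible.

## The two-stage model

A two-interval forced-choice experiment yields, per subject $i$, condition
$h$ and comparison stimulus $x_j$, a binomial count $Y_{ij}^h$ of
"comparison judged larger" responses out of $n_{ij}^h$ trials. The first
stage is a probit regression per subject and condition,

$$Y_{ij}^h \sim \mathrm{Binomial}\!\left(n_{ij}^h,\;
\Phi(\alpha_i^h + \beta_i^h x_j)\right),$$

whose two summaries are the point of subjective equality
$\mathrm{pse}_i^h = -\alpha_i^h/\beta_i^h$ (the stimulus at which the
response probability is exactly one half) and the slope $\beta_i^h$
(precision; the just-noticeable difference is inversely proportional to it).
Because the PSE is usually the quantity of scientific interest, the same
linear predictor can be written $\beta_i^h (x_j - \mathrm{pse}_i^h)$ and the
hierarchy placed on $(\mathrm{pse}_i^h, \beta_i^h)$ directly
(`parameterization = "pse_slope"`); the two forms give identical likelihoods
along $\alpha = -\mathrm{pse}\cdot\beta$, which is tested.

The second stage shrinks subjects toward condition-level (optionally
group-by-condition-level) populations:

$$\mathrm{pse}_i^h \sim N(\mathrm{PSE}^h, \tau_{\mathrm{PSE}}^h),\qquad
\beta_i^h \sim N(b^h, \tau_\beta^h),$$

$$\mathrm{PSE}^h \sim N(0, \sigma_{\mathrm{PSE}}),\quad b^h \sim N(0,
\sigma_b),\quad \tau \sim \Gamma(1, 0.001),\quad \sigma \sim \Gamma(1,
0.01).$$

**Precision convention.** Every Normal above is parameterized by mean and
*precision* (inverse variance), and every Gamma by shape and *rate* — the
conventions of the BUGS/JAGS family in which this model class is usually
programmed. The defaults above are deliberately vague on the response scales
involved; they can be overridden per model through
`psy_model(hyperpriors = ...)`.

Model variants (`build_model()`): `intercept_slope`, `pse_slope`,
`per_subject_precision` (each subject has its own $\tau_{\mathrm{PSE},i},
\tau_{\beta,i}$, letting individual reliability differ), `grouped`
(population locations and precisions indexed by group $\times$ condition,
for designs with clinical groups), and `joint` (below). Condition and group
are free-text labels ordered by first appearance; stimulus values are used
on the scale of the input file — no standardization or log transform is
applied, and none is assumed.

## Borrowing from a historical study

Two mechanisms are provided.

**Power prior** (`power_prior()`, `log_posterior_power()`): the posterior is
proportional to
$L(\theta \mid D)\, L(\theta \mid D_0)^{a_0}\, \pi_0(\theta)$ with fixed
weight $a_0 \in [0,1]$. The parameter structure is a single combined
hierarchy: population locations and all precisions are shared between the
studies, subject-level parameters are study-specific, and only the historical
*data* likelihood is raised to $a_0$. Two limits hold exactly, pointwise in
parameter space, and are tested at machine precision: $a_0 = 0$ equals the
current-only posterior and $a_0 = 1$ equals the posterior of the pooled
table.

**Slope conversion.** By Weber's law, sensitivity to speed scales inversely
with stimulus magnitude, so slopes do not transfer between studies with
different stimulus ranges. The conversion factor $c$ defaults to the ratio of
mean current to mean historical stimulus; historical subject slopes are
centered at $b^h / c$ (equivalently, the current-scale location is the
historical one times $c$). The printed form of this ratio is ambiguous in
orientation, so $c$ is an explicit argument everywhere and either orientation
can be supplied.

**Joint two-study hierarchy** (`build_joint_model()`): both studies keep
their own populations $(a^h, b^h)$ and $(a_0^h, b_0^h)$, with the current
ones centered on the historical ones, $a^h \sim N(a_0^h, \sigma_a^h)$,
$b^h \sim N(c\, b_0^h, \sigma_b^h)$; the posterior precisions
$\sigma_a^h, \sigma_b^h$ quantify agreement between the studies. In this
variant the first-stage precision hyperpriors are $\Gamma(1, 0.01)$, as that
is how this model's prior block is specified; the single-study variants use
$\Gamma(1, 0.001)$.

**Choosing $a_0$** (`power_grid()`, `select_a0()`): the model is refitted on
a grid of weights (the canonical grid is $0, 0.1, \dots, 1$), a comparison
table is assembled, and the weight minimizing the width of the population-PSE
95% credible interval is selected, ties broken toward the larger $a_0$ (more
borrowing at equal uncertainty).

## Sampler

`run_chains()` implements an adaptive Metropolis-within-Gibbs scheme written
for this model family:

* **Subject-level curves**: random-walk Metropolis, all (subject, condition)
  blocks updated simultaneously (they are conditionally independent given the
  populations), one step-size per block and parameter, adapted toward a 44%
  acceptance rate in batches of 50 during warmup and frozen afterwards.
* **Population locations and all precisions**: exact conjugate Gibbs draws
  (normal-normal and normal-Gamma full conditionals; the historical-slope
  conversion enters as a linear coefficient and preserves conjugacy).
* **Funnel moves**: centered hierarchies mix badly when a precision drifts
  high while its deviations shrink. Two extra Metropolis moves fix this: a
  *translation* move shifting a population location together with all its
  subject-level children (deviations unchanged), and a *scale* move jointly
  rescaling a precision's deviations and the precision itself
  ($\mathrm{dev}' = c\,\mathrm{dev}$, $\tau' = \tau/c^2$, with the exact
  Jacobian; the normal kernel cancels). Both are valid moves on the same
  posterior, so the sampler's contract — draws from the stated
  log-posterior — is unchanged.

Initial states are drawn independently per chain from the hyperpriors;
precision draws that would overflow (below $10^{-12}$ or above $10^{12}$)
are replaced by their prior means. One master seed drives everything;
per-chain seeds are `seed + chain - 1`, and identical inputs give
bit-identical draws. Success probabilities inside the likelihood are clamped
to $[10^{-12}, 1-10^{-12}]$ so extreme linear predictors stay finite.
Defaults are 4 chains, 5000 warmup and 5000 kept iterations; no chain
settings are inherited from elsewhere, since none are established for this
model class. The examples and tests in this package use shorter, documented
runs (typically 4 chains of 1200–1500 warmup and kept iterations for the
preset-sized designs, and a few hundred for the miniature replicate studies),
which the split R-hat shows to be ample for these posteriors.

**Convergence** (`gelman_rubin()`): split-chain, rank-normalized R-hat — each
chain is halved, draws are rank-normalized (normal scores of average ranks),
and the classic between/within variance ratio is computed on both the raw and
the folded (median-absolute) scores, reporting the larger. Constant identical
chains return exactly 1 by convention. Values at or below 1.1 are treated as
converged. Note the rank transform bounds the statistic: two completely
disjoint chains give about 1.8, not the unbounded raw-scale value — both far
beyond any sensible threshold.

## Comparison metrics

* `lppd()`: $\sum_i \log\big(\tfrac1S \sum_s p(y_i \mid \theta^{(s)})\big)$
  over binomial cells; its Monte Carlo uncertainty is reported as the
  standard deviation of per-chain lppd values. Cells whose averaged
  likelihood underflows to zero are flagged and contribute $-\infty$.
* `sum_squared_errors()`: $\sum_i (y_i/n_i - \hat p_i)^2$, with $\hat p_i$
  from each subject's posterior-mean parameters (*individual*) or from the
  population posterior means applied to every subject (*overall*).
* Log-likelihood at posterior means, at the same two levels — the only
  reading that yields one value per level, matching the two-row-per-model
  layout of the comparison tables.
* `posterior_overlap()`: both draw vectors are binned on their shared range
  (50 equal-width bins by default; the bin count is exposed because the
  statistic is mildly binning-dependent), each histogram normalized to unit
  area, and the overlap is the area under the bin-wise minimum. Identical
  histograms give 1, disjoint supports 0.
* `compare_models()` emits one individual/overall row pair per model with
  columns `model, effects, loglik, lppd, lppd_mc_error, sse, pse_ci_low,
  pse_ci_high, ci_width`; the PSE interval pools all population-level PSE
  parameters (for intercept/slope models these are derived draw-by-draw as
  $-a^h/b^h$, never as a ratio of means).

Posterior summaries use empirical percentiles with linear interpolation
(R quantile type 7) throughout.

## Synthetic data

The generator (`simulate_study()` and friends) draws subject parameters from
the second-stage normals and trial outcomes from the first-stage binomials —
exactly the generative reading of the fitted model. Two design presets
emulate the package's motivating studies:

* `touch_vibrations`: 9 participants, two masking-vibration conditions,
  seven speeds evenly spaced over 1.0–16.0 cm/s, 40 repetitions per cell
  (560 trials/participant).
* `touch_diabetes`: three groups (controls, mild, moderate) of 20
  participants, two masking conditions, five speeds evenly spaced over
  0.6–6.4 cm/s, reference 3.4 cm/s, 12 repetitions per cell
  (120 trials/participant; only the total is established, so the split into
  12 per speed-by-condition cell is this package's choice).

The exact stimulus grids of the original studies are not published, so the
presets use evenly spaced grids between the stated endpoints: they are an
emulation of those designs, not a reproduction. The paired truth fixtures
(`preset_truth()`) place unbiased observers at the reference (PSE 3.4 cm/s
for `touch_diabetes`; grid midpoint 8.5 cm/s for `touch_vibrations`, whose
reference is not established), slopes spanning roughly (0.1, 0.9) over the
grid and ordered controls > mild > moderate with masking reducing every
slope, and *low between-subject PSE spread* (sd 0.25 cm/s and 1 cm/s
respectively) with relatively larger slope spread — mirroring the repeated
empirical observation in this task family that individual PSE posteriors
overlap almost perfectly while slopes differ visibly between individuals.

What passing recovery tests on such data does **not** show about real data:
the generator has no lapses or guessing asymptotes, no learning or fatigue
drift, no adaptive stimulus placement, and its noise is exactly binomial —
so recovery results here validate the machinery, not the adequacy of the
probit-binomial model for any particular experiment.

## Numerical choices and conventions

* **JND**: beyond "inversely related to the slope", the literature uses
  several conventions; this package fixes
  `jnd_from_slope(beta) = qnorm(0.75)/beta`, half the 25–75% interquartile
  span of the fitted curve.
* Probability clamp $[10^{-12}, 1-10^{-12}]$ in all likelihood evaluations.
* The binomial coefficient is included in all log-likelihoods, so values are
  comparable across aggregation choices.
* Credible intervals: central, from interpolated empirical percentiles
  (type 7).
* `select_a0` tie-break: toward larger $a_0$.
* Degenerate inputs: a subject observed at a single stimulus level is flagged
  by `validate_trials()` as slope-unidentifiable; `beta = 0` makes the PSE
  undefined and errors; non-positive precisions make `log_prior` return
  $-\infty$ (samplers reject) rather than raising.
* Subject labels must be disjoint between current and historical studies
  (binding errors out otherwise and suggests prefixing).

## Known limitations

* **Partial-weight shrinkage.** With the power prior, only the historical
  *data* term is raised to $a_0$; historical subject-level prior terms are
  not. At intermediate weights the historical subjects' parameters are
  therefore over-shrunk toward the population mean, the between-subject
  spread is understated and the shared precision overestimated, so the
  population-PSE interval can be anticonservatively narrow at, say,
  $a_0 = 0.5$ — occasionally narrower than at $a_0 = 1$. The
  interval-width-versus-$a_0$ curve is consequently *not* guaranteed
  monotone when between-subject spread is comparable to per-subject
  estimation error (published width grids in this literature fluctuate
  non-monotonically too). The width-monotonicity test therefore probes the
  regime the borrowing mechanism targets — nearly homogeneous observers,
  where the interval is information-limited and scales as one over the
  square root of the weighted trial count.
* Probit link only (the link is an isolated function, but no alternative is
  provided); no lapse/guess-rate asymptotes; no adaptive procedures.
* The overlap statistic is histogram-based and mildly binning-dependent;
  `n_bins` is exposed.
* Random-$a_0$ (hierarchical) power priors and meta-analytic-predictive
  priors are out of scope.
* Frequentist GLMM baselines are not computed; comparison tables contain
  only this package's fits.

## Problem sizes used by the test suite

Unit tests run on miniature designs (2–8 subjects, a few hundred kept
iterations, 2 chains) chosen so the whole suite exercises every code path at
desk scale; the end-to-end checks fit the full preset designs with 4 chains
of 1200–1500 warmup and kept draws, which the split R-hat shows to be ample
for these posteriors. The parameter-recovery check uses 20 replicate fits
and requires 70% empirical coverage of nominal-95% intervals, a bound
lenient to Monte Carlo noise (under correct coverage the failure probability
is below $10^{-6}$) but sensitive to systematic errors.
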