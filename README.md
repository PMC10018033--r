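# psyborrow

Bayesian hierarchical fitting of psychometric functions for two-interval
forced-choice experiments, with historical-data borrowing through power
priors.

## The problem

A psychophysical discrimination experiment records, for each participant and
comparison stimulus magnitude *x* (e.g. surface speed in cm/s), how often the
comparison was judged larger than a reference. The psychometric function links
the stimulus to that response probability; its two summaries are the **point
of subjective equality** (PSE, the stimulus at which the response is at
chance, measuring accuracy/bias) and the **slope** (measuring precision; the
just-noticeable difference, JND, is inversely proportional to it). Fitting
each participant separately wastes the shared structure; fitting all trials
pooled understates the uncertainty. `psyborrow` fits the two-stage
hierarchical probit model

```
Y_ij^h            ~ Binomial(n_ij^h, p_ij^h)
Phi^-1(p_ij^h)    = alpha_i^h + beta_i^h x_j     (equivalently beta_i^h (x_j - pse_i^h))
alpha_i^h         ~ Normal(a^h,  tau_alpha^h)        pse_i^h ~ Normal(PSE^h, tau_PSE^h)
beta_i^h          ~ Normal(b^h,  tau_beta^h)
a^h, b^h, PSE^h   ~ Normal(0, sigma)                 tau, sigma ~ Gamma(shape, rate)
```

(indices: subject *i*, stimulus *j*, condition *h*, optionally clinical group
*k*; all Normal distributions are mean/precision, Gamma priors are shape/rate
with defaults Gamma(1, 0.001) for first-stage precisions and Gamma(1, 0.01)
for population-location precisions). Variants: intercept/slope or PSE/slope
parameterization, per-subject precisions, group-structured populations, and a
joint two-study hierarchy.

When a comparable historical study exists, a **power prior** multiplies the
posterior by the historical likelihood raised to a weight `a0` in [0, 1]
(`a0 = 0` ignores it, `a0 = 1` pools fully), with the historical slope
location rescaled by a Weber-law conversion factor (slopes scale inversely
with the stimulus-magnitude range). The weight is chosen on a grid by the
width of the population-PSE credible interval.

Posterior sampling uses an adaptive Metropolis-within-Gibbs sampler written
for this model family (conjugate draws for population locations and all
precisions, vectorized random-walk updates for subject-level curves, plus
joint translation and scale moves that cross the hierarchical funnel).
Convergence is monitored with the split rank-normalized R-hat; models are
compared by log-likelihood at posterior means, the log pointwise predictive
density (lppd), sums of squared errors at the individual and population
level, credible-interval widths, and the histogram overlap of posterior
distributions.

## Worked example

Simulate the control group of the built-in `touch_diabetes` design preset (20
participants, two masking-vibration conditions, five speeds 0.6-6.4 cm/s,
reference 3.4 cm/s, 120 trials each; unbiased observers with true PSE 3.4),
fit the PSE/slope model, and summarize:

```r
library(psyborrow)

fg  <- filter_groups(preset_design("touch_diabetes"),
                     preset_truth("touch_diabetes"), "controls")
sim <- simulate_study(fg$design, fg$truth, seed = 42)

fit <- run_chains(sim$data, build_model("pse_slope"),
                  chain_config(n_chains = 4, n_iter = 1500,
                               n_warmup = 1500, seed = 1))
fit
#> <psy_fit> pse_slope model: 90 parameters, 4 chains x 1500 draws
#>   max split R-hat: 1.007

subset(tidy(fit), grepl("^(PSE|b)\\[", parameter))
#>        parameter  mean    sd ci_low ci_high  rhat
#> 1 PSE[cond=vib0] 3.263 0.103  3.061   3.464 1.004
#> 2   b[cond=vib0] 0.403 0.024  0.356   0.450 1.004
#> 3 PSE[cond=vib1] 3.258 0.122  3.018   3.497 1.003
#> 4   b[cond=vib1] 0.321 0.023  0.277   0.367 1.003
```

Both population PSEs sit at the 3.4 cm/s reference within their credible
intervals (the observers are unbiased), while masking vibration lowers the
population slope from 0.40 to 0.32 probit units per cm/s — i.e. it raises the
JND (`jnd_from_slope`) from 1.68 to 2.10 cm/s, a loss of tactile precision
with no accuracy change. The posterior histogram overlap of the two slopes,
`posterior_overlap(draws_of(fit, "b[cond=vib0]"), draws_of(fit, "b[cond=vib1]"))`,
is 0.076: the masking effect on precision is well separated. `glance(fit)`
adds fit metrics (log-likelihood -355.3 at individual posterior means, lppd
-355.2 with 0.17 Monte Carlo error, SSE 3.18), and `compare_models()` /
`power_grid()` assemble the individual/overall comparison tables across
model variants or borrowing weights `a0`, with `select_a0()` choosing the
weight minimizing the population-PSE interval width.

A command-line interface wrapping the same functions is installed at
`inst/cli/psyborrow` (subcommands `simulate`, `fit`, `power-grid`,
`compare`), e.g.

```sh
Rscript inst/cli/psyborrow simulate --preset touch_diabetes --seed 1 --out sim/
Rscript inst/cli/psyborrow fit --data sim/trials.csv --model pse_slope --seed 1 --out fit/
```

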