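---
title: "Mixture models for continuous-report working memory data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture models for continuous-report working memory data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(circmix)
```

## The task and the models

In a continuous-report (delayed estimation) experiment, a participant briefly
views a display of `N` items (the *set size*), is probed on one of them after a
retention interval, and reports the probed feature value on a continuous
circular scale such as a colour wheel. The *response error* is the wrapped
angular deviation `e = response - target`, in radians on `(-pi, pi]`.

circmix models the distribution of these errors as a probabilistic mixture of
response modes.

**Two-component model.** With probability `1 - p_u` the response is a noisy
report of the target, modelled as a von Mises distribution (the circular
normal) centred on the target with concentration `kappa`; with probability
`p_u` it is a uniform guess:

    p(e) = (1 - p_u) * f(e; kappa) + p_u / (2 pi),

where `f(e; kappa) = exp(kappa cos e) / (2 pi I0(kappa))`. Larger `kappa`
means more precise memory; `kappa = 0` is the uniform distribution.

**Three-component model.** Binding ("swap") errors add a third mode: with
probability `p_n` the response is centred on one of the `n` non-probed items,
each equally likely and stored with the same concentration as the target:

    p(e) = (1 - p_u - p_n) * f(e; kappa) + p_u / (2 pi)
           + (p_n / n) * sum_i f(response - nontarget_i; kappa).

Setting `p_n = 0` recovers the two-component model exactly, so the models are
nested: the richer model can never fit worse, and in an AIC comparison the
two-component model can never win by more than 2 (the penalty difference for
one parameter).

**Slots and slots-plus-averaging.** These re-parameterise guessing as a
capacity limit. With `K` slots and set size `N`, a probed item is unstored
with probability `max(0, 1 - K/N)` and yields a guess (slots model). The
slots-plus-averaging (SPA) variant lets spare slots hold duplicate copies: an
item held in `m` slots is reported as the average of its copies, which divides
the representational standard deviation by `sqrt(m)`. We implement the
allocation with a single continuous rule: items carry `floor(K/N)` or
`floor(K/N) + 1` slots, a fraction `frac(K/N)` of them carrying the extra, and
zero slots means a guess. This reduces exactly to the slots model for
`K <= N`, is continuous in `K` (so `K` can be optimised without an integer
constraint), and is, in our reading, the only internally consistent
formulation of "the average value in each slot is available for report". The
`sd/sqrt(m)` averaging rule and the floor/remainder split are a design choice
isolated behind `spa_density()`; alternative allocation schemes would slot in
there.

Conversions between `kappa` and the circular standard deviation go through
the Bessel-function ratio `A(kappa) = I1(kappa)/I0(kappa)` (`kappa_to_sd()`,
`sd_to_kappa()`); the inverse is obtained by monotone root finding to 1e-10.
Bessel functions are evaluated in exponentially scaled form throughout so
concentrations of several hundred do not overflow.

## Units and data layout

Data are long-format tables, one row per trial, with configurable column
names (`read_trial_data()`, `standardise_trial_data()`). Non-target columns
are discovered by a shared prefix. Three angular units are accepted:
`degrees` (full circle, 1-360), `degrees_180` (axial data such as bar
orientations, 1-180) and `radians`. Everything is converted internally to
radians on `(-pi, pi]`. Axial data are doubled onto the full circle before
analysis — the standard treatment, since orientations 180 degrees apart are
identical — so fitted `kappa` lives in the doubled space, and error-scaled
summary statistics (mean absolute error, bias) are halved back on output.
When no set-size column is present, per-trial set size is inferred as one
plus the number of non-missing non-targets, which makes single-condition
files usable without extra metadata.

## Model-free summary statistics

`get_summary_statistics()` returns, per participant by set size by condition:
mean absolute error (radians, in `[0, pi]`), resultant vector length of the
errors (1 = identical responses, 0 = fully dispersed), bias (circular mean of
signed errors), and precision — the reciprocal circular standard deviation
`1/sqrt(-2 log R)` minus its expectation under pure guessing for the same
trial count. That chance term has, to our knowledge, no convenient closed
form, so it is estimated once per trial count by seeded Monte Carlo (10,000
uniform samples, fixed internal seed, cached); repeated calls are
deterministic and the user's RNG stream is never touched. For small cells the
Monte-Carlo estimate may differ from other implementations in the third
decimal. Degenerate cells are handled explicitly: a resultant length at
numerical zero is reported as infinite circular SD rather than an error.

## Fitting

`fit_mixture_model()` maximises the likelihood per cell (participant by
set size by condition) with Nelder-Mead, run from every point of a fixed
start grid to avoid local minima: `kappa` in {1, 10, 100} crossed with
`p_u` (and `p_n`) in {0.01, 0.1, 0.4} — 9 starts for the two-component
model, 27 for the three-component model. The slots models use `K` in
{1, 2, 4} crossed with the `kappa` values, a grid of our own construction
spanning plausible capacities. Numerical choices:

* The search runs unconstrained: `log(kappa)` (bounded to `(1e-3, 1e4)`),
  and an additive-log-ratio transform of `(p_t, p_u, p_n)`, keeping the
  simplex constraint implicit and the objective smooth.
* Convergence tolerance `reltol = 1e-8`, at most 2000 iterations per start;
  the best converged start wins, ties going to the earliest in grid order.
* The likelihood kernel is compiled (C++), evaluates in log space with
  log-sum-exp mixing and scaled Bessel functions, and is cross-checked in
  the test suite against the plain-R density functions.
* Cells whose trials all have set size 1 carry no non-targets; the
  three-component model is fitted there with `p_n` fixed at 0.

With `return_fit = TRUE` each cell also reports the log-likelihood, trial
count, and AIC / AICc / BIC. `compare_models()` scores the AIC and BIC
differences with the orientation `two-component minus three-component`
(positive favours the three-component model) and flags differences below the
nesting bound of -2 as optimiser failures.

A caveat worth knowing: like all finite mixtures with a free concentration,
the likelihood is unbounded — a component can collapse onto a single
response that happens to sit arbitrarily close to its centre. With few
trials per cell (around 50 or fewer) the global optimum occasionally is such
a spike (very large `kappa`, most mass assigned to guessing). The `kappa`
bound caps these solutions rather than eliminating them; we deliberately
report the maximum-likelihood answer instead of silently regularising.
Expect noisy `kappa` estimates in small cells, and treat estimates at the
`kappa` bound as a sign that the cell is under-sampled.

## Simulating

`simulate_responses()` generates trial tables from any of the four models.
Stimulus values are drawn on the integer-degree colour-wheel grid (1-360),
reflecting how such experiments are typically programmed; responses are
continuous. Per trial a latent response mode is drawn (target / specific
non-target / guess) with the model's probabilities, and the response is a von
Mises draw around the chosen item (Best-Fisher rejection sampling), or
uniform for guesses. Three spacing policies control the display:
uniform sampling without replacement (default, no separation constraint),
exact consecutive spacing from a random start with the probe assigned
uniformly among the items, and a minimum pairwise separation drawn by an
exact gap-composition sampler (equivalent to rejection sampling but fast
even near the feasibility limit). Multiple set sizes are interleaved with
equal allocation (remainder to the earliest) and per-set-size parameter
vectors.

What the simulator emulates is the *measurement model itself* under an
idealised observer: stationary parameters, independent trials, no response
bias, no sequential or motor effects, no stimulus-similarity structure
beyond item positions. Passing recovery tests therefore demonstrates that
the fitting machinery inverts the generative model faithfully — not that
real data satisfy these assumptions.

## The simulation-study harness

Three study drivers reproduce the standard design-analysis workflow, all
driven by a single master seed that spawns per-participant/per-dataset
substream seeds (runs are serial and bit-reproducible):

* `run_parameter_recovery()` — simulate synthetic participants with
  parameters drawn uniformly (defaults: `kappa` 1-16, `p_u` 0-0.4, `p_n`
  0-0.14), refit, and report the product-moment correlation between
  generating and recovered values, labelled poor / fair / good / excellent
  at thresholds .5 / .75 / .9 (boundary values take the higher label).
* `run_tradeoff_study()` — sweep one parameter over an equally spaced grid
  (`kappa` 4-12, `p_u` 0.05-0.80, `p_n` 0.05-0.80; 50 points by default)
  holding the others at `kappa = 8`, `p_u = 0.10`, `p_n = 0.15`, and
  summarise every recovered parameter at every point.
* `run_model_recovery()` — simulate from a known generating model, fit both
  mixture models, and score AIC/BIC differences and percent-correct model
  selection.

The set size defaults to 4 in all drivers, and in the fixed-spacing policy
the probe's position within the array is randomised — both points on which
the underlying designs are commonly left unstated.

The test suite runs these studies at the sizes a reviewer can wait for: 500
synthetic participants for the recovery designs (50-500 trials each), 200
datasets per generating model for model recovery, and a 100,000-trial
simulator consistency check; the acceptance script
(`scripts/acceptance.R`) uses the same sizes. Each full run takes minutes,
not hours, on a single core.

## Known limitations

* Maximum-likelihood point estimates only: no hierarchical pooling across
  participants, and no standard errors on parameters. Cells need enough
  trials to stand on their own (200 or more per cell is a sensible floor
  for stable three-component estimates).
* `p_n` is weakly identified when non-targets lie close to the target in
  feature space: with 5-degree spacing the swap and target components are
  nearly indistinguishable at typical concentrations, and recovered `p_n`
  values are then dominated by estimation noise. Separations of 40 degrees
  or more make swap errors cleanly attributable.
* The small-cell likelihood degeneracy described under *Fitting*.
* The response-bias term (a free mean for the target component) is not
  modelled; errors are assumed centred on the reported item.
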