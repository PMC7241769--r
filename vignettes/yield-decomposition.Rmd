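---
title: "Decomposing eDNA protocol yield: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing eDNA protocol yield: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednaopt)
```

## The problem

An environmental DNA (eDNA) assay for a water sample is a chain of partial
recoveries: a filter captures some fraction of the target copies suspended
in the water, an extraction chemistry recovers some fraction of what the
filter holds, carried-over PCR inhibitors (humic matter, proteases) make
some fraction of the recovered copies unavailable to amplification unless a
secondary inhibitor-removal (SIR) column is added, and finally qPCR
quantifies what survives, with non-detects below a cycle ceiling. Labs
choosing among filter membranes, extraction kits and cleanup steps need the
per-step efficiencies, not just end-to-end comparisons, because cost and
hands-on time are also incurred per step. `ednaopt` implements the full
analysis loop for factorial protocol-comparison experiments: simulation,
quantification, Bayesian yield decomposition, model comparison, step
importance and cost/time/yield ranking.

## The model

For an observation with filter $f$, extraction $e$ and SIR indicator $s$,
the observed yield fraction $Y$ (recovered copies / input copies) is modeled
as

$$Y \sim \mathrm{Normal}\!\left(\mu_{f,e,s},\ \sigma\right), \qquad
\mu_{f,e,s} = \max\!\big(0,\; Y_f\,(Y_e + \delta_{f,e}) - I_f I_e\,[s = 0]\big)$$

* $Y_f \in [0,1]$: fraction of input copies the filter captures;
* $Y_e \in [0,1]$: fraction of filter-bound copies the extraction recovers;
* $I_f, I_e \in [0,1]$: inhibitor carryover attributable to filter and
  extraction; their *product* is the fraction of input lost to inhibition
  when SIR is skipped;
* $\delta_{f,e}$: filter-by-extraction interference offsets, constrained to
  sum to zero across filters within each extraction so that the extraction
  main effects stay identified. The *no-interference* variant fixes
  $\delta \equiv 0$; fitting both variants and comparing them by WAIC/LOO is
  how step independence is tested.

Clipping $\mu$ at zero encodes total inhibition: when the inhibitor product
exceeds the available yield the expected recovery is zero copies, which is
what fully-censored no-SIR cells (e.g. a harsh NaOH extraction) look like in
real data.

**Likelihood and censoring.** The factorial "$\sim$" relation does not by
itself fix an error law; we use homoscedastic Normal noise on the yield
fraction, the simplest choice consistent with occasional exact-zero
recoveries. A qPCR non-detect is a left-censored observation: its
contribution is $\Phi\!\big((L - \mu)/\sigma\big)$, where $L$ is the
detection limit of the standard curve expressed as a yield fraction
(`censoring = FALSE` turns non-detects into exact zeros instead). The
generator's noise is multiplicative lognormal, so the fitted model is
mildly misspecified at the small-yield end — deliberate, since a fitted
model never matches the data-generating process exactly in practice; the
misspecification costs efficiency, not consistency, in our recovery tests.

**Priors.** All yield and carryover fractions get flat Beta(1, 1) priors on
$[0,1]$ (logistic density on the logit scale); interference offsets get
Normal(0, 0.05); $\sigma$ gets a Half-Normal whose scale defaults to twice
the SD of the detected yields.

## Identifiability and the calibration anchor

End-to-end yields identify only the products $Y_f Y_e$: multiplying every
filter yield by $c$ and dividing every extraction yield by $c$ changes no
$\mu$. The same holds for $I_f I_e$. This is a property of the experiment,
not of the inference — absolute per-step fractions require external
calibration. The package therefore adds one **scale anchor**: a Gaussian
prior on the logit capture ratio of a single reference filter
(`priors$anchor_level`, default the first filter alphabetically, centred at
`anchor_mean = 0.00107` with `anchor_sd = 0.15`, i.e. roughly ±30% at 95%).
The default centre is a published glass-fiber capture ratio for estuarine
water; a lab with its own spike-calibration estimate should substitute it.
Every ratio, ranking, SIR effect, and WAIC/LOO comparison is invariant to
the anchor; only the absolute split between filter and extraction scales
depends on it. The inhibitor split is *not* anchored: report and interpret
the product $I_f I_e$ (as `sir_effect()` does), not its factors.

A sharper corollary: a SIR-incompatible extraction (the direct-to-qPCR
dipstick) has no SIR arm, so even the product $Y_f Y_e$ is not directly
observed for it — only $Y_f Y_e - I_f I_e$. Its extraction yield is then
confounded with its carryover, weakly separated only by cross-filter
contrasts. Its marginal posterior is wide and right-skewed; the posterior
*mean* overstates the yield even though the interval covers the truth. This
is a structural limit of the design, visible in our recovery study (the
acceptance suite leaves the bias check for that one parameter red on
purpose), and the reason the mean-based fold-change statements for dipstick
methods should not be trusted from this kind of experiment.

## Inference

The default fitter is automatic-differentiation variational inference with
a **full-rank** Gaussian on the unconstrained scale, initialized from a MAP
optimum and its Laplace covariance, and refined with Adam on the
reparameterized ELBO (analytic gradients throughout; the test suite checks
them against numerical differentiation). Mean-field ADVI is available but
not the default: the product ridge induces strong correlations between
$\mathrm{logit}\,Y_f$ and $\mathrm{logit}\,Y_e$ that a factorized family
cannot represent, and in our recovery experiments mean-field intervals
undercover exactly as that argument predicts. An adaptive random-walk
Metropolis sampler (Haario covariance adaptation plus Robbins–Monro scale
tuning toward 0.234 acceptance) serves as an independent cross-check; the
suite asserts ADVI and MCMC agree on filter-yield posterior means to within
0.1 posterior SD on a strongly identified fixture.

Numerical choices: parameters live on logit/log scales with box bounds
±25 during MAP; the ELBO optimizer drops non-finite gradients and clamps
its state to ±35 so divergent runs stay finite and are reported by the
ELBO-drift diagnostic (relative drift of the last two deciles above 1%
raises a warning, never a silent failure); the Laplace covariance floors
eigenvalues so fully-censored cells (flat likelihood directions) get
prior-scale variance rather than breaking the Cholesky.

## Model comparison

`compute_waic()` and `compute_loo()` consume the pointwise log-likelihood
matrix attached to every fit. WAIC uses the variance over draws with $1/S$
normalization, which matches the Monte Carlo mean in the lppd term and
makes the criterion exactly invariant under duplication of draws. LOO uses
Pareto-smoothed importance sampling: raw ratios $\exp(-\ell_{d,i})$, a
generalized-Pareto fit (Zhang–Stephens profile likelihood with the usual
weak prior on the shape) to the largest $\min(0.2S, 3\sqrt S)$ weights,
replacement of the tail by expected order statistics, truncation at the
maximum raw weight, and a per-observation $\hat k$ diagnostic (flagged
above 0.7). `refit_loo()` provides the brute-force oracle path — one refit
per left-out observation — used to validate PSIS on small problems.
`model_weights()` computes pseudo-BMA weights
($w_m \propto \exp(\mathrm{elpd}_m)$) by default and stacking weights
(simplex optimization of the pointwise predictive density) on request; at
the large elpd gaps seen in variant selection both round identically.

## What the synthetic generator emulates — and what it does not

`simulate_experiment()` reproduces the statistical structure the analysis
assumes: a 3-filter × 5-extraction × optional-SIR factorial (27 protocols
once the direct-to-qPCR dipstick is excluded from the SIR arm — it skips
the elution the cleanup column needs), 3 biological replicates each, 3
controls (84 samples), technical qPCR triplicates, a 40-cycle ceiling,
logistic amplification probability in log10 copies, Normal Cq noise
(default 0.25 cycles) around a standard curve, multiplicative lognormal
noise (default CV 0.10) on recovered copies, lognormal per-sample input
copies (mean 1e6, CV 0.3 — chosen so that most protocol cells sit
comfortably above the detection limit, as in a tank-spiked experiment, while
the weakest cells flirt with censoring), and per-filter filtration-time
draws matching measured estuarine means. Default per-step efficiencies are
published posterior means for this assay family; default carryovers are
chosen to reproduce the qualitative pattern that nitrocellulose carries the
most filtration inhibitors and that NaOH extraction without SIR never
amplifies. Determinism: every sample draws from an RNG stream derived from
`(seed, sample index)`, so identical seeds give identical tables
independent of generation order.

Not emulated: sequence content (no reads, only copy-number bookkeeping),
hydrology/turbidity mechanics (filtration times are drawn, not modeled),
plate/batch effects, and between-day drift. A green test therefore
establishes that the estimators recover the truth of *this* stated world at
the study's design size — not that a field survey with unmodeled batch
structure would behave as well.

## Protocol scoring and recommendation

`score_protocols()` applies the step decomposition to catalog means, sums
per-sample costs, and accounts hands-on time as batch time divided by batch
size (unattended incubations are excluded — they cost no labor). Detection
probability is evaluated at a reference input concentration through the
logistic amplification model. Ranking is by yield, ties broken by time then
cost. `recommend_protocol()` walks an ordered, data-driven rule table
(YAML-loadable) rather than hard-coded branching; the built-in `balanced`
strategy encodes the published decision-tree reasoning — fastest filter for
turbid water, extractions that are neither inhibitor-prone
(catalog carryover ≤ 0.05) nor in the subpar half of the yield range, SIR
retained when compatible, then the fastest remaining protocol — which under
the default catalog selects glass fiber + magnetic beads + SIR. Catalog
costs and most batch times are editable defaults, not measurements: only
the filtration times and the 77-minutes-per-18-samples silica-column figure
are anchored to reported numbers.

## Known limitations

* Absolute per-step yields are calibration-dependent (see the anchor
  discussion); cross-study comparisons should be made on ratios.
* The SIR-incompatible extraction's yield is structurally confounded with
  its carryover; trust its interval, not its posterior mean.
* The shared, additive noise SD underweights small-yield cells when yields
  span orders of magnitude; a scale-dependent noise model would be the next
  refinement.
* PSIS-LOO diagnostics ($\hat k$) should be checked before trusting LOO
  weights on datasets with influential single observations; `refit_loo()`
  is the fallback.
* The random-forest importance is computed on one-hot factors with
  group-wise permutation; with only three design factors it answers "which
  step explains yield variance in this factorial", not a general
  variable-selection question.
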