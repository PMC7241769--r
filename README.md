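# ednaopt — protocol optimization for environmental DNA assays

`ednaopt` is an R package for labs designing environmental DNA (eDNA)
monitoring protocols — for example, detecting a fish species in turbid
estuarine water from the DNA it sheds. An eDNA protocol is a chain of
partial recoveries (water filtration → DNA extraction → optional secondary
PCR-inhibitor removal (SIR) → qPCR), and choosing among filter membranes,
extraction chemistries and cleanup steps means trading DNA yield against
cost and hands-on time. The package provides the full analysis loop for
factorial protocol-comparison experiments:

* a **seeded synthetic-experiment generator** with the design structure
  such studies use (3 filters × 5 extractions × ±SIR = 27 protocols, 3
  biological replicates, controls, technical qPCR triplicates, 40-cycle
  ceiling with non-detects);
* **qPCR quantification**: standard-curve fitting, Cq ↔ copy-number
  conversion, censored yield observations, spike-in input estimation,
  logistic amplification-probability and concentration–yield regressions;
* a **Bayesian yield decomposition** fitted by full-rank ADVI (adaptive
  MCMC as a cross-check). For filter *f*, extraction *e*, SIR indicator
  *s*:

  $$Y \sim \mathrm{Normal}\big(\max(0,\; Y_f (Y_e + \delta_{f,e}) - I_f I_e\,[s{=}0]),\ \sigma\big)$$

  with left-censoring at the detection limit; the no-interference variant
  fixes the offsets δ to zero;
* **model comparison**: WAIC and PSIS-LOO with pseudo-BMA and stacking
  weights, plus an exact refit-LOO oracle; random-forest **step
  importance**; ranking-stability checks;
* **protocol decision support**: per-step cost/time catalogs, yield /
  detection-probability / cost / time scoring, and a rule-table
  recommendation engine encoding the published decision-tree guidance.

See `vignettes/yield-decomposition.Rmd` for the model, its identifiability
(why absolute per-step yields need a calibration anchor) and all numerical
choices.

## Worked example

```r
library(ednaopt)

truth  <- truth_config(seed = 1L)          # published per-method means
design <- design_config()                  # 27 protocols x 3 reps + controls
experiment <- simulate_experiment(truth, design)   # 84 rows with Cq values
yields <- compute_yields(experiment)

fit <- fit_yield_model(
  build_yield_model(yields, yield_model_spec("no_interference")),
  iterations = 3000L, mc_samples = 8L, seed = 1L)
fit
#> Yield-decomposition fit (advi, no_interference variant): 2000 draws
#>             parameter     mean       sd     q2.5    q97.5
#>            Y_f[glass] 1.01e-03 1.14e-04 8.02e-04 1.25e-03
#>   Y_f[nitrocellulose] 1.73e-03 2.06e-04 1.36e-03 2.17e-03
#>          Y_f[whatman] 4.50e-04 5.96e-05 3.47e-04 5.75e-04
#>            Y_e[beads] 2.16e-01 2.66e-02 1.69e-01 2.70e-01
#>          Y_e[qiagen] 4.75e-01 5.13e-02 3.77e-01 5.75e-01
#>   ...
```

The filter posteriors recover the generative truth (0.00107 / 0.00172 /
0.00045 for glass / nitrocellulose / Whatman). Fold-changes come with
draw-wise intervals:

```r
r <- posterior_yield_ratio(fit, "Y_f[nitrocellulose]", "Y_f[glass]")
sprintf("nitrocellulose vs glass capture: %.2f-fold (95%% CI %.2f-%.2f)",
        r$ratio_of_means, r$interval[1], r$interval[2])
#> "nitrocellulose vs glass capture: 1.72-fold (95% CI 1.60-1.86)"
```

Which protocol step matters most, and what should a lab actually run?

```r
step_importance(yields, seed = 1L)
#>       factor  permutation permutation_q2.5 permutation_q97.5  impurity
#> 1 extraction 5.153245e-08     1.463654e-08      9.776642e-08 0.5930728
#> 2     filter 2.409079e-08    -2.066217e-09      5.573518e-08 0.2810069
#> 3        sir 1.228139e-08    -5.396494e-09      4.033390e-08 0.1259203

recommend_protocol(score_protocols())
#> Recommended protocol: glass + beads + SIR
#>   expected yield 0.00022, detection p 0.976, cost 4.50, 2.83 min/sample
#>   rule fired: balanced_default
```

The extraction step dominates yield variance (so it is where further
optimization pays off), and under the default cost/time catalog the
balanced recommendation is glass-fiber filtration + magnetic beads + an
inhibitor-removal column — the combination that best trades yield against
speed in turbid water.

Comparing the interference and no-interference model variants with
`compute_waic()` / `compute_loo()` and `model_weights()` reproduces the
selection of the no-interference model with weight 1
(`tests/testthat/test-acceptance.R`).

## Command-line interface

`inst/cli/ednaopt.R` exposes the pipeline as subcommands:

```sh
Rscript inst/cli/ednaopt.R simulate --seed 3 --out out/
Rscript inst/cli/ednaopt.R quantify --samples out/experiment.csv --out out/yields.csv
Rscript inst/cli/ednaopt.R fit --yields out/yields.csv --variant no_interference --seed 1 --out out/fit
Rscript inst/cli/ednaopt.R rank --out out/ranking.csv
```

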