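# Shared fixtures, memoised so expensive posterior fits are computed once
# per test run.

fixture_env <- new.env(parent = emptyenv())

fixture_truth <- function() truth_config(seed = 7L)

fixture_yields <- function() {
  if (is.null(fixture_env$yields)) {
    fixture_env$yields <- compute_yields(
      simulate_experiment(fixture_truth(), design_config()))
  }
  fixture_env$yields
}

# default-design fit of the no-interference model, reused across tests
fixture_fit <- function() {
  if (is.null(fixture_env$fit)) {
    m <- build_yield_model(fixture_yields(),
                           yield_model_spec("no_interference"))
    fixture_env$fit <- fit_yield_model(m, iterations = 3000L,
                                       mc_samples = 8L, seed = 11L)
  }
  fixture_env$fit
}

# a small, strongly identified truth on the 0.1-0.5 yield scale, used where
# tests need visible inhibitor effects or fast ADVI/MCMC agreement
big_yield_truth <- function(filter_inhibitor = c(fA = 0.25, fB = 0.25),
                            extraction_inhibitor = c(eX = 0.2, eY = 0.2),
                            obs_noise_sd = 0.10, seed = 3L) {
  truth_config(filter_yield = c(fA = 0.30, fB = 0.20),
               extraction_yield = c(eX = 0.50, eY = 0.25),
               filter_inhibitor = filter_inhibitor,
               extraction_inhibitor = extraction_inhibitor,
               obs_noise_sd = obs_noise_sd,
               input_copies_mean = 1e6, input_copies_cv = 0,
               seed = seed)
}

big_yield_design <- function(replicates = 3L) {
  design_config(filters = c("fA", "fB"), extractions = c("eX", "eY"),
                sir_incompatible = character(0), replicates = replicates,
                controls = character(0),
                filtration_time = list(fA = c(2, 0.1), fB = c(3, 0.1)))
}

big_yield_spec <- function(variant = "no_interference", ...) {
  yield_model_spec(variant,
                   priors = list(anchor_level = "fA", anchor_mean = 0.30,
                                 anchor_sd = 0.15),
                   ...)
}
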