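# Yield-decomposition model: parameter bookkeeping, gradient and likelihood
# oracles, prior behaviour, SIR effects, and ADVI/MCMC agreement.

test_that("parameter bookkeeping matches the two variants", {
  y <- fixture_yields()
  m0 <- build_yield_model(y, yield_model_spec("no_interference"))
  m1 <- build_yield_model(y, yield_model_spec("interference"))
  # F + E + F + E + 1 with F = 3, E = 5
  expect_equal(n_parameters(m0), 17)
  # interference adds one offset per filter x extraction cell...
  expect_equal(n_parameters(m1), 17 + 15)
  # ...of which E are absorbed by the zero-sum constraint
  expect_equal(n_parameters(m1, free = TRUE), 17 + 10)
  expect_equal(m1$n_free, 27)
  # controls never enter the model
  expect_equal(nrow(m0$data), 81)
})

test_that("single-level factors are rejected as unidentifiable", {
  y <- fixture_yields()
  one <- y[y$filter == "glass", ]
  expect_error(build_yield_model(one, yield_model_spec()), "2 filters")
})

test_that("analytic gradient matches numerical differentiation", {
  y <- fixture_yields()
  for (variant in c("no_interference", "interference")) {
    m <- build_yield_model(y, yield_model_spec(variant))
    th0 <- ednaopt:::map_init(m)
    for (s in 1:3) {
      th <- th0 + with_seed(s, stats::rnorm(m$n_free, 0, 0.4))
      ga <- m$grad(th)
      gn <- numDeriv::grad(m$log_post, th)
      expect_lt(max(abs(ga - gn) / (1 + abs(gn))), 1e-6)
    }
  }
})

test_that("pointwise log-density equals a scalar reimplementation to 1e-8", {
  fit <- fixture_fit()
  m <- fit$model
  set.seed(41)
  pairs <- cbind(sample(nrow(fit$zdraws), 100, replace = TRUE),
                 sample(nrow(m$data), 100, replace = TRUE))
  for (k in seq_len(nrow(pairs))) {
    d <- pairs[k, 1]; i <- pairs[k, 2]
    pp <- m$transform(fit$zdraws[d, ])
    f <- m$data$filter[i]; e <- m$data$extraction[i]
    mu <- max(0, pp$Y_f[[f]] * (pp$Y_e[[e]] + pp$delta[f, e]) -
                (if (m$data$sir[i]) 0 else pp$I_f[[f]] * pp$I_e[[e]]))
    ll_ref <- if (m$data$censored[i]) {
      stats::pnorm(m$data$limit[i], mu, pp$sigma, log.p = TRUE)
    } else {
      stats::dnorm(m$data$y[i], mu, pp$sigma, log = TRUE)
    }
    expect_equal(fit$loglik[d, i], ll_ref, tolerance = 1e-8)
  }
})

test_that("posterior draws respect the [0,1] supports exactly", {
  fit <- fixture_fit()
  frac <- fit$draws[, grepl("^[YI]_", colnames(fit$draws))]
  expect_true(all(frac >= 0 & frac <= 1))
  expect_true(all(fit$draws[, "sigma"] > 0))
})

test_that("with SIR on every observation the inhibitor posterior is the prior", {
  tr <- big_yield_truth()
  ex <- simulate_experiment(tr, big_yield_design())
  y <- compute_yields(ex)
  y <- y[y$sir, ]
  m <- build_yield_model(y, big_yield_spec())
  fit <- fit_yield_model(m, iterations = 2000L, seed = 2L)
  icols <- grepl("^I_", fit$summary$parameter)
  # Beta(1,1) prior: mean 1/2, sd sqrt(1/12) ~ 0.289
  expect_true(all(abs(fit$summary$mean[icols] - 0.5) < 0.12))
  expect_true(all(fit$summary$sd[icols] > 0.15))
})

test_that("zero-inhibitor data concentrate the inhibitor product near zero", {
  tr <- big_yield_truth(filter_inhibitor = c(fA = 0, fB = 0),
                        extraction_inhibitor = c(eX = 0, eY = 0))
  y <- compute_yields(simulate_experiment(tr, big_yield_design()))
  fit <- fit_yield_model(build_yield_model(y, big_yield_spec()),
                         iterations = 2000L, seed = 2L)
  prod_mean <- mean(fit$draws[, "I_f[fA]"] * fit$draws[, "I_e[eX]"])
  expect_lt(prod_mean, 0.25)   # below the Beta(1,1) product prior mean
  expect_lt(prod_mean, 0.05)
  eff <- sir_effect(fit)
  expect_true(all(eff$effect_mean < 0.05))
})

test_that("sir_effect recovers a 0.05 inhibitor product and flags censored methods", {
  # truth with I_f * I_e = 0.05 against yields large enough to see it
  tr <- big_yield_truth()   # 0.25 * 0.2 = 0.05 for every pair
  y <- compute_yields(simulate_experiment(tr, big_yield_design()))
  fit <- fit_yield_model(build_yield_model(y, big_yield_spec()),
                         iterations = 3000L, mc_samples = 8L, seed = 4L)
  eff <- sir_effect(fit)
  expect_true(all(eff$effect_q2.5 <= 0.05 & 0.05 <= eff$effect_q97.5))
  expect_true(all(abs(eff$effect_mean - 0.05) < 0.04))

  # default truth: NaOH without SIR is fully inhibited -> flagged
  eff_d <- sir_effect(fixture_fit())
  naoh <- eff_d[eff_d$extraction == "naoh", ]
  expect_true(all(naoh$sir_essential))
  qia <- eff_d[eff_d$extraction == "qiagen", ]
  expect_false(any(qia$sir_essential))
})

test_that("posterior_yield_ratio handles fits, mean vectors and identity", {
  fit <- fixture_fit()
  r <- posterior_yield_ratio(fit, "Y_f[nitrocellulose]", "Y_f[nitrocellulose]")
  expect_equal(r$ratio_of_means, 1)
  expect_equal(r$mean_ratio, 1)
  means <- c("Y_e[qiagen]" = 0.475, "Y_e[naoh]" = 0.287)
  expect_equal(posterior_yield_ratio(means, "Y_e[qiagen]",
                                     "Y_e[naoh]")$ratio_of_means,
               0.475 / 0.287)
  expect_error(posterior_yield_ratio(fit, "Y_f[bogus]", "sigma"), "bogus")
})

test_that("ADVI and MCMC agree on filter-yield posteriors", {
  tr <- big_yield_truth(seed = 13L)
  y <- compute_yields(simulate_experiment(tr, big_yield_design(replicates = 5L)))
  m <- build_yield_model(y, big_yield_spec())
  fa <- fit_yield_model(m, iterations = 8000L, mc_samples = 8L, seed = 3L)
  fm <- fit_yield_model(m, method = "mcmc", iterations = 120000L, seed = 3L)
  for (p in c("Y_f[fA]", "Y_f[fB]")) {
    da <- fa$summary[fa$summary$parameter == p, ]
    dm <- fm$summary[fm$summary$parameter == p, ]
    expect_lt(abs(da$mean - dm$mean), 0.1 * max(da$sd, dm$sd))
  }
})

test_that("non-convergent ADVI warns rather than failing silently", {
  y <- fixture_yields()
  m <- build_yield_model(y, yield_model_spec("no_interference"))
  # an absurd step size keeps the ELBO oscillating, which the drift
  # heuristic must surface instead of returning silently
  expect_warning(fit_yield_model(m, iterations = 300L, seed = 1L,
                                 learning_rate = 5),
                 "converged|drift")
})
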