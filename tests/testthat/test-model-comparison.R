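# WAIC / PSIS-LOO against brute-force oracles, model weights, random-forest
# step importance and ranking-stability checks.

test_that("WAIC equals a scalar brute-force evaluation of its formula", {
  ll <- matrix(c(-1.2, -0.7, -1.9,
                 -2.1, -0.3, -1.4), nrow = 3)   # 3 draws x 2 observations
  res <- compute_waic(ll)
  # independent scalar oracle: explicit loops, no shared code
  oracle_elpd <- 0
  for (i in 1:2) {
    lppd_i <- log(mean(exp(ll[, i])))
    p_i <- mean((ll[, i] - mean(ll[, i]))^2)  # 1/S variance over draws
    oracle_elpd <- oracle_elpd + lppd_i - p_i
  }
  expect_equal(res$elpd, oracle_elpd, tolerance = 1e-10)
  expect_equal(sum(res$pointwise$elpd), res$elpd, tolerance = 1e-12)

  # zero-variance draws: p_waic = 0 and lppd = sum of the constants
  cc <- matrix(rep(c(-1.3, -0.4), each = 4), nrow = 4)
  res_c <- compute_waic(cc)
  expect_equal(res_c$p_eff, 0)
  expect_equal(res_c$lppd, -1.3 - 0.4)

  # duplicating every draw changes nothing
  expect_equal(compute_waic(rbind(ll, ll))$elpd, res$elpd,
               tolerance = 1e-12)

  expect_error(compute_waic(matrix(c(1, NA), 2, 1)), "finite")
  expect_error(compute_waic(matrix(-1, 1, 3)), ">= 2 draws")
})

test_that("LOO degenerates to lppd for identical draws and never exceeds it", {
  cc <- matrix(rep(c(-1.3, -0.4), each = 10), nrow = 10)
  res <- compute_loo(cc)
  expect_equal(res$elpd, res$lppd, tolerance = 1e-10)
  expect_equal(res$p_eff, 0, tolerance = 1e-10)

  for (s in 1:5) {
    ll <- with_seed(s, matrix(stats::rnorm(400, -1, 0.7), 50, 8))
    r <- compute_loo(ll)
    expect_lte(r$elpd, r$lppd + 1e-9)
    expect_gte(r$p_eff, -1e-9)
  }
})

test_that("PSIS-LOO matches exact refit LOO on a conjugate toy", {
  # y_i ~ N(mu, 1), mu ~ N(0, 1): posterior and LOO predictive are closed
  # form, so refits are exact and cheap
  y <- c(-1.1, 0.4, 1.9, 0.3, -0.6, 1.2)
  fitter <- function(data) {
    data <- unlist(data)
    n <- length(data)
    vn <- 1 / (n + 1)
    mn <- sum(data) * vn
    with_seed(101L + n, stats::rnorm(4000, mn, sqrt(vn)))
  }
  logdensity <- function(draws, datum) stats::dnorm(unlist(datum), draws, 1, log = TRUE)

  exact <- refit_loo(as.list(y), fitter, logdensity)
  full_draws <- fitter(y)
  ll <- vapply(y, function(yi) logdensity(full_draws, yi),
               numeric(length(full_draws)))
  psis <- compute_loo(ll)
  expect_lt(abs(psis$elpd - exact$elpd), 0.5)
  expect_true(all(psis$diagnostics$pareto_k < 0.7))

  # analytic check of the exact path itself: p(y_i | y_-i) is Normal
  n <- length(y)
  analytic <- sum(vapply(seq_along(y), function(i) {
    vi <- 1 / n; mi <- sum(y[-i]) * vi
    stats::dnorm(y[i], mi, sqrt(1 + vi), log = TRUE)
  }, numeric(1)))
  expect_lt(abs(exact$elpd - analytic), 0.1)
})

test_that("model weights: ties, dominance, equivariance and stacking", {
  ll_a <- matrix(rep(-1, 20), 10, 2)
  res_a <- compute_waic(ll_a)
  w_tie <- model_weights(list(m1 = res_a, m2 = res_a))
  expect_equal(unname(w_tie), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(w_tie), 1, tolerance = 1e-9)

  ll_b <- ll_a - 10   # elpd lower by 20
  res_b <- compute_waic(ll_b)
  w_dom <- model_weights(list(good = res_a, bad = res_b))
  expect_gt(w_dom[["good"]], 0.999)

  # permutation equivariance
  w_rev <- model_weights(list(bad = res_b, good = res_a))
  expect_equal(w_rev[["good"]], w_dom[["good"]], tolerance = 1e-12)

  w_stack <- model_weights(list(good = res_a, bad = res_b),
                           method = "stacking")
  expect_gt(w_stack[["good"]], 0.9)
  expect_equal(sum(w_stack), 1, tolerance = 1e-9)

  expect_error(model_weights(list(res_a)), ">= 2")
  expect_error(model_weights(list(a = res_a, b = compute_waic(ll_a[, 1,
                                                                   drop = FALSE]))),
               "same observations")
})

test_that("no-interference truth selects the simpler model in most seeded runs", {
  # scaled-down version of the design-size selection study: 6 seeds with a
  # reduced ADVI budget; the full design-size single-seed reproduction lives
  # in the acceptance suite
  wins <- 0L
  for (s in 1:6) {
    y <- compute_yields(simulate_experiment(truth_config(seed = 300L + s),
                                            design_config()))
    f0 <- fit_yield_model(build_yield_model(y, yield_model_spec("no_interference")),
                          iterations = 1500L, seed = s)
    f1 <- fit_yield_model(build_yield_model(y, yield_model_spec("interference")),
                          iterations = 1500L, seed = s)
    w <- model_weights(list(no_int = compute_waic(f0$loglik),
                            int = compute_waic(f1$loglik)))
    if (w[["no_int"]] > 0.8) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("step importance singles out a dominant extraction effect", {
  # construct a factorial where extraction yields vary 10-fold, filters are
  # identical and SIR does nothing
  grid <- expand.grid(filter = c("f1", "f2", "f3"),
                      extraction = paste0("e", 1:5),
                      sir = c(TRUE, FALSE), rep = 1:3,
                      stringsAsFactors = FALSE)
  e_effect <- c(e1 = 0.05, e2 = 0.1, e3 = 0.2, e4 = 0.35, e5 = 0.5)
  grid$yield <- e_effect[grid$extraction] *
    with_seed(55L, exp(stats::rnorm(nrow(grid), 0, 0.05)))
  grid$censored <- FALSE
  imp <- step_importance(grid, seed = 9L, num_trees = 300L)
  expect_equal(imp$factor[1], "extraction")
  expect_gt(imp$permutation[imp$factor == "extraction"],
            2 * max(imp$permutation[imp$factor != "extraction"]))
  # null factors: resampling interval straddles zero
  for (f in c("filter", "sir")) {
    expect_lte(imp$permutation_q2.5[imp$factor == f], 1e-12)
  }
  # determinism under identical seeds
  imp2 <- step_importance(grid, seed = 9L, num_trees = 300L)
  expect_identical(imp, imp2)
  # impurity shares are a normalized decomposition
  expect_equal(sum(imp$impurity), 1, tolerance = 1e-9)
})

test_that("ranking stability is detected, and broken by strong interference", {
  y <- fixture_yields()
  chk <- rank_independence_check(y)
  expect_true(chk$filters_stable)
  expect_true(chk$extractions_stable)
  # the fully-inhibited NaOH no-SIR cells flag their strata
  expect_true(any(grepl("naoh", chk$flagged_strata)))

  # constructed counterexample: one extraction reverses the filter order
  grid <- expand.grid(filter = c("fa", "fb"), extraction = c("ex", "ey"),
                      rep = 1:3, stringsAsFactors = FALSE)
  grid$sir <- TRUE
  base <- c(fa = 0.4, fb = 0.2)
  swapped <- stats::setNames(rev(base), names(base))
  grid$yield <- ifelse(grid$extraction == "ex", base[grid$filter],
                       swapped[grid$filter])
  grid$censored <- FALSE
  chk2 <- rank_independence_check(grid)
  expect_false(chk2$filters_stable)

  # single stratum is trivially stable
  one <- grid[grid$extraction == "ex", ]
  expect_true(rank_independence_check(one)$filters_stable)
})
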