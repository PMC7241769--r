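# Protocol enumeration, cost/time accounting, ranking and recommendation.

test_that("default catalog enumerates exactly 27 protocols", {
  prot <- enumerate_protocols()
  expect_equal(nrow(prot), 27L)
  expect_equal(anyDuplicated(prot), 0L)
  # composition: 3 filters x (4 SIR-compatible x 2 + 1 incompatible)
  expect_equal(sum(prot$sir), 3 * 4)
  expect_false(any(prot$sir & prot$extraction == "direct_dipstick"))
  # deterministic order
  expect_identical(prot, enumerate_protocols())
})

test_that("enumeration count follows the closed form for arbitrary catalogs", {
  make_catalog <- function(nf, ne, n_incompat, with_sir = TRUE) {
    rows <- list()
    for (i in seq_len(nf)) {
      rows[[length(rows) + 1]] <- data.frame(
        method = paste0("f", i), kind = "filtration", cost = 1,
        batch_time_min = 5, batch_size = 4L, mean_yield = 0.001,
        inhibitor = 0.01, sir_compatible = TRUE)
    }
    for (i in seq_len(ne)) {
      rows[[length(rows) + 1]] <- data.frame(
        method = paste0("e", i), kind = "extraction", cost = 1,
        batch_time_min = 10, batch_size = 8L, mean_yield = 0.3,
        inhibitor = 0.01, sir_compatible = i > n_incompat)
    }
    if (with_sir) {
      rows[[length(rows) + 1]] <- data.frame(
        method = "sir", kind = "sir", cost = 2, batch_time_min = 10,
        batch_size = 10L, mean_yield = 1, inhibitor = 0,
        sir_compatible = NA)
    }
    do.call(rbind, rows)
  }
  for (s in 1:5) {
    dims <- with_seed(s, c(sample(1:4, 1), sample(1:5, 1)))
    ni <- with_seed(s + 5, sample(0:dims[2], 1))
    cat <- make_catalog(dims[1], dims[2], ni)
    expect_equal(nrow(enumerate_protocols(cat)),
                 dims[1] * (2 * (dims[2] - ni) + ni))
  }
  # 1 filter, 1 compatible extraction -> 2 protocols
  expect_equal(nrow(enumerate_protocols(make_catalog(1, 1, 0))), 2L)
  # all extractions SIR-incompatible -> filters x extractions
  expect_equal(nrow(enumerate_protocols(make_catalog(3, 4, 4))), 12L)
  # no SIR step in the catalog: same count
  expect_equal(nrow(enumerate_protocols(make_catalog(2, 3, 0,
                                                     with_sir = FALSE))), 6L)
})

test_that("scores combine per-step batch time, cost and the yield identity", {
  cat <- default_step_catalog()
  sc <- score_protocols(enumerate_protocols(cat), cat)
  row <- sc[sc$filter == "glass" & sc$extraction == "qiagen" & !sc$sir, ]
  # silica-column extraction: 77 minutes / 18 samples = 4.278 min/sample
  expect_equal(row$time_per_sample_min, 2.32 / 4 + 77 / 18, tolerance = 1e-9)
  expect_equal(row$expected_yield, 0.00107 * 0.475 - 0.008 * 0.004,
               tolerance = 1e-12)
  expect_equal(row$cost_per_sample, 0.50 + 3.50)

  # ranking is a strict total order on ranks
  expect_identical(sort(sc$rank), seq_len(nrow(sc)))
  expect_true(all(diff(sc$expected_yield) <= 1e-15))

  # removing SIR never increases expected yield
  for (i in which(sc$sir)) {
    twin <- sc[sc$filter == sc$filter[i] & sc$extraction == sc$extraction[i] &
                 !sc$sir, ]
    expect_lte(twin$expected_yield, sc$expected_yield[i] + 1e-15)
  }
})

test_that("cost accounting is linear and zero-preserving", {
  cat <- default_step_catalog()
  zero <- cat; zero$cost <- 0
  sc0 <- score_protocols(enumerate_protocols(zero), zero)
  expect_true(all(sc0$cost_per_sample == 0))

  dbl <- cat; dbl$cost <- 2 * dbl$cost
  sc1 <- score_protocols(enumerate_protocols(cat), cat)
  sc2 <- score_protocols(enumerate_protocols(dbl), dbl)
  expect_equal(sc2$cost_per_sample, 2 * sc1$cost_per_sample)
  expect_identical(sc2[, c("filter", "extraction", "sir", "rank")],
                   sc1[, c("filter", "extraction", "sir", "rank")])
})

test_that("recommendations follow the decision rules", {
  sc <- score_protocols()
  # unconstrained yield maximization: the top-yield protocol
  r1 <- recommend_protocol(sc, list(objective = "max_yield"))
  expect_equal(r1$protocol[, c("filter", "extraction", "sir")],
               data.frame(filter = "nitrocellulose", extraction = "qiagen",
                          sir = TRUE),
               ignore_attr = TRUE)
  expect_equal(r1$rule, "maximize_yield_unconstrained")

  # balanced default: fast glass filtration + magnetic beads + SIR
  r2 <- recommend_protocol(sc)
  expect_equal(r2$protocol[, c("filter", "extraction", "sir")],
               data.frame(filter = "glass", extraction = "beads",
                          sir = TRUE),
               ignore_attr = TRUE)
  expect_false(r2$best_effort)
  expect_true(any(grepl("balanced_default.*fired", r2$trace)))

  # infeasible cost cap: best-effort flag with nearest-feasible protocol
  r3 <- recommend_protocol(sc, list(max_cost = 0.01))
  expect_true(r3$best_effort)
  expect_s3_class(r3$protocol, "data.frame")

  # severe-but-feasible cost constraint pushes to dipstick-class protocols
  r4 <- recommend_protocol(sc, list(max_cost = 1))
  expect_equal(r4$rule, "severe_cost_constraint")
  expect_true(r4$protocol$extraction %in% c("dipstick", "direct_dipstick"))
})

test_that("catalog and rules survive CSV / YAML round trips", {
  cat <- default_step_catalog()
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(cat), tmp, row.names = FALSE)
  back <- read_step_catalog(tmp)
  expect_equal(as.data.frame(back), as.data.frame(cat))

  rules <- default_decision_rules()
  ytmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(rules, unclass), ytmp)
  back_rules <- read_decision_rules(ytmp)
  sc <- score_protocols()
  expect_equal(recommend_protocol(sc, rules = back_rules)$protocol,
               recommend_protocol(sc, rules = rules)$protocol)
})
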