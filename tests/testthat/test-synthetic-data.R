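# Synthetic experiment generator: exact noise-free arithmetic, seeding
# contract, design enumeration, and the conservation/monotonicity
# properties of the step decomposition.

noise_free_truth <- function(yf, ye, iff, ie, seed = 1L) {
  truth_config(filter_yield = c(fA = yf), extraction_yield = c(eA = ye),
               filter_inhibitor = c(fA = iff),
               extraction_inhibitor = c(eA = ie),
               obs_noise_sd = 0, input_copies_mean = 1e6,
               input_copies_cv = 0, seed = seed)
}

one_cell_design <- function() {
  design_config(filters = "fA", extractions = "eA",
                sir_incompatible = character(0), replicates = 3L,
                controls = character(0),
                filtration_time = list(fA = c(2, 0.1)))
}

test_that("noise-free recovery follows the step decomposition exactly", {
  ex <- simulate_experiment(noise_free_truth(0.5, 0.5, 0.3, 0.4),
                            one_cell_design())
  # SIR arm: inhibitor indicator off, recovered = N * Yf * Ye = 250000
  expect_equal(ex$recovered_copies[ex$sir], rep(250000, 3))
  # no-SIR arm: Yf*Ye = 0.25, If*Ie = 0.12 -> fraction 0.13
  expect_equal(unique(ex$true_fraction[!ex$sir]), 0.13)

  # subtraction example: Yf*Ye = 0.25, If*Ie = 0.05 -> fraction 0.20
  ex2 <- simulate_experiment(noise_free_truth(0.5, 0.5, 0.25, 0.2),
                             one_cell_design())
  expect_equal(unique(ex2$true_fraction[!ex2$sir]), 0.20)
  expect_equal(ex2$recovered_copies[!ex2$sir], rep(2e5, 3))

  # total inhibition clips to zero copies, not negative
  ex3 <- simulate_experiment(noise_free_truth(0.01, 0.01, 0.9, 0.9),
                             one_cell_design())
  expect_true(all(ex3$recovered_copies[!ex3$sir] == 0))
  expect_true(all(is.na(ex3$cq_1[!ex3$sir])))
})

test_that("seeding contract: identical seeds identical tables, new seed new Cq", {
  de <- design_config()
  a <- simulate_experiment(truth_config(seed = 42L), de)
  b <- simulate_experiment(truth_config(seed = 42L), de)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_experiment(truth_config(seed = 43L), de)
  expect_false(identical(a$cq_1, c$cq_1))
})

test_that("full default design yields 27 protocols x 3 replicates + 3 controls = 84 rows", {
  ex <- simulate_experiment(truth_config(seed = 1L), design_config())
  expect_equal(nrow(ex), 84L)
  expect_equal(sum(ex$is_control), 3L)
  prot <- unique(ex[!ex$is_control, c("filter", "extraction", "sir")])
  expect_equal(nrow(prot), 27L)
  # negative controls carry zero target copies and never amplify
  neg <- ex[ex$is_control & grepl("negative", ex$control_type), ]
  expect_true(all(neg$input_copies == 0))
  expect_true(all(is.na(neg$cq_1)))
})

test_that("unknown method names raise a configuration error naming the key", {
  tr <- truth_config(seed = 1L)
  de <- design_config(filters = c("glass", "mystery_filter"))
  expect_error(simulate_experiment(tr, de), "mystery_filter")
})

test_that("conservation and SIR monotonicity hold under random truths", {
  de <- design_config(replicates = 2L)
  for (s in 1:5) {
    fy <- with_seed(s, stats::runif(3, 0, 1))
    ey <- with_seed(s + 10, stats::runif(5, 0, 1))
    tr <- truth_config(
      filter_yield = stats::setNames(fy, .default_filters),
      extraction_yield = stats::setNames(ey, .default_extractions),
      filter_inhibitor = stats::setNames(with_seed(s + 20, stats::runif(3)),
                                         .default_filters),
      extraction_inhibitor = stats::setNames(
        with_seed(s + 30, stats::runif(5)), .default_extractions),
      obs_noise_sd = 0.5, seed = s)
    ex <- simulate_experiment(tr, de)
    expect_true(all(ex$recovered_copies <= ex$input_copies + 1e-9))
    # expected fraction with SIR >= without, per protocol
    cells <- unique(ex[!ex$is_control, c("filter", "extraction")])
    for (i in seq_len(nrow(cells))) {
      sub <- ex[ex$filter == cells$filter[i] &
                  ex$extraction == cells$extraction[i] & !ex$is_control, ]
      if (all(c(TRUE, FALSE) %in% sub$sir)) {
        expect_gte(unique(sub$true_fraction[sub$sir]),
                   unique(sub$true_fraction[!sub$sir]))
      }
    }
  }
})

test_that("simulate_qpcr: sentinels, curve arithmetic and logistic midpoint", {
  curve <- standard_curve(slope = -3.3219, intercept = 38, sigma_cq = 0)
  always <- amplification_model(a = 50, b = 0)  # p = 1 at any concentration

  expect_true(is.na(simulate_qpcr(0, curve, always, seed = 1L)))
  expect_equal(simulate_qpcr(1e3, curve, always, seed = 1L),
               38 - 3.3219 * 3)

  # copies whose expected Cq exceeds the ceiling are non-detects
  expect_true(is.na(simulate_qpcr(0.01, curve, always, seed = 1L)))

  # at the logistic midpoint ~50% of reactions amplify
  amp <- amplification_model(a = -4, b = 2)   # midpoint at 100 copies
  cq <- simulate_qpcr(rep(100, 10000), standard_curve(sigma_cq = 0.25),
                      amp, seed = 99L)
  expect_equal(mean(!is.na(cq)), 0.5, tolerance = 0.04)

  expect_error(simulate_qpcr(-5, curve, always), ">= 0")
})

test_that("round trip: cq_to_copies inverts simulation at zero noise", {
  curve <- standard_curve(sigma_cq = 0)
  always <- amplification_model(a = 50, b = 0)
  copies <- 10^seq(1, 6, by = 0.5)
  cq <- simulate_qpcr(copies, curve, always, seed = 2L)
  expect_equal(cq_to_copies(cq, curve), copies, tolerance = 1e-6)
})

test_that("spike series carries known inputs through the reference protocol", {
  tr <- truth_config(seed = 5L, input_copies_cv = 0.1)
  sp <- simulate_spike_series(tr, design_config(), replicates = 3L)
  expect_equal(nrow(sp), 9L)
  expect_setequal(unique(sp$spike_ng_per_l), c(1, 0.1, 0.01))
  expect_true(all(sp$filter == "glass" & sp$extraction == "qiagen" & sp$sir))
})
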