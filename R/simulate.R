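# Seeded generator for synthetic multi-step eDNA recovery experiments.
# Copy-number bookkeeping only: input copies -> filter capture -> extraction
# recovery -> (optional) inhibitor loss -> qPCR Cq with censoring at the
# cycle ceiling. No sequence-level simulation.

# Expected recovered fraction for one protocol under a truth configuration.
expected_fraction <- function(truth, filter, extraction, sir) {
  yf <- truth$filter_yield[[filter]]
  ye <- truth$extraction_yield[[extraction]] +
    truth$interference_offset[filter, extraction]
  ye <- min(max(ye, 0), 1)
  loss <- if (sir) 0 else
    truth$filter_inhibitor[[filter]] * truth$extraction_inhibitor[[extraction]]
  # negative expected yield = total inhibition, clipped to zero copies
  max(0, yf * ye - loss)
}

#' Simulate qPCR measurement of a copy number
#'
#' A reaction amplifies with probability `p_amp(copies)` (logistic in log10
#' copies); when it does, the observed Cq is the standard-curve expectation
#' plus Normal technical noise. Amplification failure, zero input copies, or
#' a Cq beyond the cycle ceiling all return `NA` (the non-detect sentinel).
#'
#' @param copies non-negative starting copy numbers (vectorized).
#' @param curve an [standard_curve()]; supplies intercept/slope, the Cq noise
#'   SD and the cycle ceiling.
#' @param amp an [amplification_model()].
#' @param seed optional integer; when given, draws use a private RNG stream.
#' @return numeric vector of Cq values with `NA` for non-detects.
#' @export
simulate_qpcr <- function(copies, curve = standard_curve(),
                          amp = amplification_model(), seed = NULL) {
  if (any(copies < 0, na.rm = TRUE)) stop_config("copies must be >= 0")
  draw <- function() {
    n <- length(copies)
    p <- amplification_probability(copies, amp)
    amplified <- stats::runif(n) < p
    cq <- rep(NA_real_, n)
    idx <- which(amplified & copies > 0)
    if (length(idx)) {
      cq[idx] <- copies_to_cq(copies[idx], curve) +
        stats::rnorm(length(idx), 0, curve$sigma_cq)
      cq[idx][cq[idx] > curve$max_cycles] <- NA_real_
    }
    cq
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Internal: simulate one biological sample (input draw, latent recovery,
# technical qPCR replicates) on its own derived RNG stream.
simulate_sample_rows <- function(truth, design, curve, amp, frac,
                                 input_mean, stream_seed) {
  with_seed(stream_seed, {
    n_in <- rlnorm_cv(1, input_mean, truth$input_copies_cv)
    recovered <- if (input_mean <= 0 || frac <= 0) {
      n_in * frac
    } else {
      # conservation: noise cannot push recovery above the physical input
      min(n_in * frac * rlnorm_cv(1, 1, truth$obs_noise_sd), n_in)
    }
    cq <- simulate_qpcr(rep(recovered, design$tech_replicates), curve, amp)
    list(input_copies = n_in, recovered_copies = recovered, cq = cq)
  })
}

#' Simulate a full factorial protocol-comparison experiment
#'
#' Generates one row per biological replicate of every enumerated protocol
#' (full factorial of filter x extraction x SIR, SIR-incompatible
#' extractions excluded from the SIR arm), plus the configured controls.
#' Latent recovered copies follow
#' `N_in * max(0, Y_f * (Y_e + offset) - I_f * I_e * [no SIR])` perturbed by
#' multiplicative lognormal noise; Cq values come from [simulate_qpcr()].
#' Negative controls carry zero target copies. Identical seeds reproduce
#' identical tables; every sample draws from a stream derived from
#' `(truth$seed, sample index)`, so tables are reproducible row by row.
#'
#' @param truth an [truth_config()].
#' @param design an [design_config()].
#' @param curve standard curve used to turn copies into Cq.
#' @param amp amplification-probability model.
#' @return data.frame of class `edna_experiment`: protocol assignment,
#'   replicate, true input and latent recovered copies, filtration time and
#'   `cq_1..cq_K` technical-replicate columns. The `curve` and `amp` objects
#'   are attached as attributes for downstream quantification.
#' @export
simulate_experiment <- function(truth, design = design_config(),
                                curve = standard_curve(max_cycles = design$max_cycles),
                                amp = amplification_model()) {
  stopifnot(inherits(truth, "edna_truth"), inherits(design, "edna_design"))
  check_truth_design(truth, design)

  prots <- enumerate_protocol_grid(design$filters, design$extractions,
                                   design$sir_incompatible)
  grid <- prots[rep(seq_len(nrow(prots)), each = design$replicates), ]
  grid$replicate <- rep(seq_len(design$replicates), nrow(prots))

  n_prot_rows <- nrow(grid)
  n_ctrl <- length(design$controls)
  n <- n_prot_rows + n_ctrl
  ref_filter <- design$filters[1]
  ref_extraction <- design$extractions[1]

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (i <= n_prot_rows) {
      f <- grid$filter[i]; e <- grid$extraction[i]; s <- grid$sir[i]
      rep_i <- grid$replicate[i]
      ctrl <- NA_character_
      input_mean <- truth$input_copies_mean
    } else {
      # controls run through the reference protocol; negatives carry no
      # target DNA, the tank-only positive carries twice the mixed input
      j <- i - n_prot_rows
      f <- ref_filter; e <- ref_extraction; s <- TRUE
      rep_i <- 1L
      ctrl <- names(design$controls)[j]
      input_mean <- if (design$controls[[j]] == "negative") 0 else
        2 * truth$input_copies_mean
    }
    frac <- expected_fraction(truth, f, e, s)
    sim <- simulate_sample_rows(truth, design, curve, amp, frac,
                                input_mean, derive_seed(truth$seed, i))
    ft <- design$filtration_time[[f]]
    ftime <- with_seed(derive_seed(truth$seed, i + n), {
      max(0.1, stats::rnorm(1, ft[1], ft[2]))
    })
    row <- data.frame(sample_id = sprintf("S%03d", i),
                      filter = f, extraction = e, sir = s,
                      replicate = rep_i,
                      is_control = !is.na(ctrl),
                      control_type = ctrl,
                      input_copies = sim$input_copies,
                      true_fraction = frac,
                      recovered_copies = sim$recovered_copies,
                      filtration_time_min = ftime,
                      stringsAsFactors = FALSE)
    cqs <- as.list(sim$cq)
    names(cqs) <- sprintf("cq_%d", seq_along(cqs))
    rows[[i]] <- cbind(row, cqs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curve") <- curve
  attr(out, "amp") <- amp
  attr(out, "design") <- design
  class(out) <- c("edna_experiment", "data.frame")
  out
}

#' Simulate a standard-curve dilution ladder
#'
#' @param curve the true curve generating the ladder.
#' @param levels copy numbers of the dilution series.
#' @param replicates technical replicates per level.
#' @param seed integer seed.
#' @return data.frame with columns `copies` and `cq` (non-detects dropped
#'   would bias the fit; the ladder is simulated with amplification
#'   probability 1, as dilution ladders use concentrations far above the
#'   detection limit).
#' @export
simulate_standard_ladder <- function(curve = standard_curve(),
                                     levels = 10^(1:6), replicates = 1L,
                                     seed = 1L) {
  copies <- rep(levels, each = replicates)
  cq <- with_seed(seed, {
    copies_to_cq(copies, curve) + stats::rnorm(length(copies), 0, curve$sigma_cq)
  })
  data.frame(copies = copies, cq = cq)
}

#' Simulate a spike-in series through a reference protocol
#'
#' Emulates the input-estimation experiment: surface-water samples spiked at
#' known concentrations, processed with a fixed reference protocol (first
#' filter + first extraction + SIR by default), and measured by qPCR.
#'
#' @param truth an [truth_config()].
#' @param design an [design_config()]; supplies the spike series (ng/L).
#' @param copies_per_ng conversion from nanograms of target to copies
#'   (default 4.6e9, a ~200 bp double-stranded fragment).
#' @param replicates samples per concentration (default 3).
#' @param filter,extraction,sir reference protocol (defaults: first filter,
#'   first extraction, SIR used).
#' @param curve,amp measurement models as in [simulate_experiment()].
#' @return `edna_experiment`-style data.frame with a `spike_ng_per_l` column.
#' @export
simulate_spike_series <- function(truth, design = design_config(),
                                  copies_per_ng = 4.6e9, replicates = 3L,
                                  filter = design$filters[1],
                                  extraction = design$extractions[1],
                                  sir = TRUE,
                                  curve = standard_curve(max_cycles = design$max_cycles),
                                  amp = amplification_model()) {
  check_truth_design(truth, design)
  conc <- rep(design$spike_concentrations, each = replicates)
  frac <- expected_fraction(truth, filter, extraction, sir)
  rows <- vector("list", length(conc))
  for (i in seq_along(conc)) {
    input_mean <- conc[i] * copies_per_ng
    sim <- simulate_sample_rows(truth, design, curve, amp, frac, input_mean,
                                derive_seed(truth$seed, 10000L + i))
    row <- data.frame(sample_id = sprintf("SPK%02d", i),
                      filter = filter, extraction = extraction, sir = sir,
                      replicate = ((i - 1L) %% replicates) + 1L,
                      is_control = FALSE, control_type = NA_character_,
                      spike_ng_per_l = conc[i],
                      input_copies = sim$input_copies,
                      true_fraction = frac,
                      recovered_copies = sim$recovered_copies,
                      stringsAsFactors = FALSE)
    cqs <- as.list(sim$cq)
    names(cqs) <- sprintf("cq_%d", seq_along(cqs))
    rows[[i]] <- cbind(row, cqs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curve") <- curve
  attr(out, "amp") <- amp
  class(out) <- c("edna_experiment", "data.frame")
  out
}
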