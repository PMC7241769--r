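# Configuration objects describing the generative "truth" of a synthetic
# protocol-comparison experiment and the factorial design layout.

# Canonical method names used by the default design: three filter membranes
# and five extraction chemistries. "direct_dipstick" is dipped straight into
# the qPCR reaction and therefore cannot be followed by a column-based
# secondary inhibitor removal (SIR) step.
.default_filters <- c("glass", "nitrocellulose", "whatman")
.default_extractions <- c("qiagen", "beads", "naoh", "dipstick",
                          "direct_dipstick")

#' Generative truth for a synthetic eDNA recovery experiment
#'
#' Defines the latent per-step efficiencies from which synthetic experiments
#' are simulated. Total realized yield for a sample follows the step
#' decomposition
#' \deqn{Y = \max(0,\; Y_f (Y_e + \delta_{f,e}) - I_f I_e \,[\mathrm{no\ SIR}])}
#' where \eqn{Y_f} is the fraction of input eDNA copies captured by the
#' filter, \eqn{Y_e} the fraction of filter-bound DNA recovered by the
#' extraction, \eqn{I_f I_e} the fraction of input rendered unavailable by
#' carried-over PCR inhibitors when no secondary inhibitor removal (SIR) is
#' performed, and \eqn{\delta_{f,e}} an optional filter-by-extraction
#' interference offset (identically zero under the no-interference truth).
#'
#' Default efficiencies are the published per-method posterior means for this
#' kind of estuarine protocol comparison (filter capture on the 1e-3 scale,
#' extraction recovery 0.05-0.48); inhibitor carryover defaults encode the
#' qualitative pattern that nitrocellulose carries the most filtration
#' inhibitors and NaOH extraction fails entirely without SIR.
#'
#' @param filter_yield named fractions in \[0,1\]: capture ratio per filter.
#' @param extraction_yield named fractions in \[0,1\]: recovery per extraction.
#' @param filter_inhibitor named fractions in \[0,1\]: inhibitor carryover
#'   attributable to the filter (\eqn{I_f}).
#' @param extraction_inhibitor named fractions in \[0,1\]: inhibitor carryover
#'   attributable to the extraction (\eqn{I_e}).
#' @param interference_offset numeric matrix (filters x extractions) of signed
#'   offsets \eqn{\delta_{f,e}} added to \eqn{Y_e}; 0 = no interference.
#' @param obs_noise_sd coefficient of variation of multiplicative lognormal
#'   noise on recovered copies (default 0.10).
#' @param input_copies_mean mean target copies per sample entering filtration.
#' @param input_copies_cv coefficient of variation of the per-sample input.
#' @param seed integer root seed; per-sample streams are derived from it.
#' @return An object of class `edna_truth`.
#' @export
truth_config <- function(filter_yield = c(glass = 0.00107,
                                          nitrocellulose = 0.00172,
                                          whatman = 0.00045),
                         extraction_yield = c(qiagen = 0.475,
                                              beads = 0.206,
                                              naoh = 0.287,
                                              dipstick = 0.047,
                                              direct_dipstick = 0.132),
                         filter_inhibitor = c(glass = 0.008,
                                              nitrocellulose = 0.025,
                                              whatman = 0.010),
                         extraction_inhibitor = c(qiagen = 0.004,
                                                  beads = 0.004,
                                                  naoh = 0.080,
                                                  dipstick = 0.002,
                                                  direct_dipstick = 0.004),
                         interference_offset = NULL,
                         obs_noise_sd = 0.10,
                         input_copies_mean = 1e6,
                         input_copies_cv = 0.3,
                         seed = 1L) {
  check_fraction(filter_yield, "filter_yield")
  check_fraction(extraction_yield, "extraction_yield")
  check_fraction(filter_inhibitor, "filter_inhibitor")
  check_fraction(extraction_inhibitor, "extraction_inhibitor")
  if (is.null(names(filter_yield)) || is.null(names(extraction_yield))) {
    stop_config("filter_yield and extraction_yield must be named vectors")
  }
  if (!setequal(names(filter_yield), names(filter_inhibitor))) {
    stop_config("filter_yield and filter_inhibitor must name the same filters")
  }
  if (!setequal(names(extraction_yield), names(extraction_inhibitor))) {
    stop_config("extraction_yield and extraction_inhibitor must name the same methods")
  }
  if (is.null(interference_offset)) {
    interference_offset <- matrix(
      0, length(filter_yield), length(extraction_yield),
      dimnames = list(names(filter_yield), names(extraction_yield)))
  } else {
    interference_offset <- as.matrix(interference_offset)
    if (!identical(sort(rownames(interference_offset)),
                   sort(names(filter_yield))) ||
        !identical(sort(colnames(interference_offset)),
                   sort(names(extraction_yield)))) {
      stop_config("interference_offset must have filter rows and extraction columns")
    }
  }
  if (obs_noise_sd < 0 || input_copies_mean <= 0 || input_copies_cv < 0) {
    stop_config("noise and input-copy settings must be non-negative (mean > 0)")
  }
  structure(list(filter_yield = filter_yield,
                 extraction_yield = extraction_yield,
                 filter_inhibitor = filter_inhibitor,
                 extraction_inhibitor = extraction_inhibitor,
                 interference_offset = interference_offset,
                 obs_noise_sd = obs_noise_sd,
                 input_copies_mean = input_copies_mean,
                 input_copies_cv = input_copies_cv,
                 seed = as.integer(seed)),
            class = "edna_truth")
}

#' Factorial design layout for a protocol-comparison experiment
#'
#' Describes the crossed design: every filter x extraction combination run
#' with and without SIR (except SIR-incompatible extractions), a fixed number
#' of biological replicates per protocol, and named controls. With the
#' default 3 filters, 5 extractions and one SIR-incompatible extraction the
#' design enumerates 3 x (4 x 2 + 1) = 27 protocols; with 3 replicates and 3
#' controls that is 84 samples.
#'
#' @param filters character vector of filter names.
#' @param extractions character vector of extraction-method names.
#' @param sir_incompatible extraction methods that cannot be followed by SIR
#'   (they skip the elution step the cleanup column needs).
#' @param replicates biological replicates per protocol (default 3).
#' @param tech_replicates qPCR technical replicates per sample (default 3).
#' @param controls named character vector of control descriptors; names are
#'   sample labels, values one of "negative"/"positive".
#' @param spike_concentrations spike-in series in ng/L used by the
#'   input-estimation experiment.
#' @param filtration_time named list per filter of `c(mean, sd)` minutes to
#'   filter one sample (defaults follow measured estuarine filtration times).
#' @param max_cycles qPCR cycle ceiling (default 40).
#' @return An object of class `edna_design`.
#' @export
design_config <- function(filters = .default_filters,
                          extractions = .default_extractions,
                          sir_incompatible = "direct_dipstick",
                          replicates = 3L,
                          tech_replicates = 3L,
                          controls = c(negative_di = "negative",
                                       positive_tank = "positive",
                                       negative_slough = "negative"),
                          spike_concentrations = c(1, 0.1, 0.01),
                          filtration_time = list(
                            glass = c(2.32, 0.08),
                            nitrocellulose = c(14.16, 1.86),
                            whatman = c(6.72, 1.99)),
                          max_cycles = 40L) {
  if (!all(sir_incompatible %in% extractions)) {
    stop_config("sir_incompatible names unknown extraction(s): %s",
                paste(setdiff(sir_incompatible, extractions), collapse = ", "))
  }
  if (anyDuplicated(filters) || anyDuplicated(extractions)) {
    stop_config("filters and extractions must be unique")
  }
  if (replicates < 1 || tech_replicates < 1) {
    stop_config("replicates and tech_replicates must be >= 1")
  }
  missing_ft <- setdiff(filters, names(filtration_time))
  for (f in missing_ft) filtration_time[[f]] <- c(5, 1)
  structure(list(filters = filters,
                 extractions = extractions,
                 sir_incompatible = sir_incompatible,
                 replicates = as.integer(replicates),
                 tech_replicates = as.integer(tech_replicates),
                 controls = controls,
                 spike_concentrations = spike_concentrations,
                 filtration_time = filtration_time,
                 max_cycles = as.integer(max_cycles)),
            class = "edna_design")
}

#' @export
print.edna_truth <- function(x, ...) {
  cat("Synthetic-truth configuration\n")
  cat("  filters:    ", paste(sprintf("%s=%g", names(x$filter_yield),
                                      x$filter_yield), collapse = ", "), "\n")
  cat("  extractions:", paste(sprintf("%s=%g", names(x$extraction_yield),
                                      x$extraction_yield), collapse = ", "), "\n")
  cat("  interference:", if (all(x$interference_offset == 0)) "none"
      else "present", "\n")
  cat(sprintf("  obs noise CV %.3g; input copies %.3g (CV %.3g); seed %d\n",
              x$obs_noise_sd, x$input_copies_mean, x$input_copies_cv, x$seed))
  invisible(x)
}

#' @export
print.edna_design <- function(x, ...) {
  n_prot <- length(x$filters) *
    (2 * sum(!x$extractions %in% x$sir_incompatible) +
       sum(x$extractions %in% x$sir_incompatible))
  cat(sprintf(
    "Factorial eDNA design: %d filters x %d extractions (+/- SIR) = %d protocols\n",
    length(x$filters), length(x$extractions), n_prot))
  cat(sprintf("  %d biological x %d technical replicates; %d controls; %d qPCR cycles\n",
              x$replicates, x$tech_replicates, length(x$controls), x$max_cycles))
  invisible(x)
}

# Cross-check that the truth and design agree on method names.
check_truth_design <- function(truth, design) {
  bad_f <- setdiff(design$filters, names(truth$filter_yield))
  bad_e <- setdiff(design$extractions, names(truth$extraction_yield))
  if (length(bad_f)) {
    stop_config("design filter(s) missing from truth_config: %s",
                paste(bad_f, collapse = ", "))
  }
  if (length(bad_e)) {
    stop_config("design extraction(s) missing from truth_config: %s",
                paste(bad_e, collapse = ", "))
  }
  invisible(TRUE)
}
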