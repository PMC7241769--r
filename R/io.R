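# Plain-text interchange: experiment tables and yields as CSV, truth/design
# configuration as YAML, standard curves as small JSON sidecars.

#' Write / read an experiment table
#'
#' The CSV holds one row per biological replicate with protocol assignment
#' and `cq_*` columns; the measurement models (standard curve and
#' amplification model) travel in a JSON sidecar `<path>.meta.json` so a
#' round trip preserves everything quantification needs.
#'
#' @param experiment an `edna_experiment`.
#' @param path CSV destination.
#' @export
write_experiment <- function(experiment, path) {
  utils::write.csv(as.data.frame(experiment), path, row.names = FALSE)
  curve <- attr(experiment, "curve"); amp <- attr(experiment, "amp")
  if (!is.null(curve)) {
    meta <- list(curve = curve[c("slope", "intercept", "sigma_cq",
                                 "max_cycles")],
                 amp = if (!is.null(amp)) amp[c("a", "b")] else NULL)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(d, "curve") <- standard_curve(slope = meta$curve$slope,
                                       intercept = meta$curve$intercept,
                                       max_cycles = meta$curve$max_cycles,
                                       sigma_cq = meta$curve$sigma_cq)
    if (!is.null(meta$amp)) {
      attr(d, "amp") <- amplification_model(a = meta$amp$a, b = meta$amp$b)
    }
  }
  class(d) <- c("edna_experiment", "data.frame")
  d
}

#' Read truth / design configuration from YAML
#'
#' The YAML mirrors the arguments of [truth_config()] / [design_config()];
#' absent fields keep their defaults.
#' @param path YAML file.
#' @export
read_truth_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("filter_yield", "extraction_yield", "filter_inhibitor",
               "extraction_inhibitor")) {
    if (!is.null(cfg[[nm]])) args[[nm]] <- unlist(cfg[[nm]])
  }
  for (nm in c("obs_noise_sd", "input_copies_mean", "input_copies_cv",
               "seed")) {
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  }
  if (!is.null(cfg$interference_offset)) {
    args$interference_offset <- do.call(rbind, lapply(cfg$interference_offset,
                                                      unlist))
  }
  do.call(truth_config, args)
}

#' @rdname read_truth_config
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("filters", "extractions", "sir_incompatible", "replicates",
               "tech_replicates", "spike_concentrations", "max_cycles")) {
    if (!is.null(cfg[[nm]])) {
      args[[nm]] <- unlist(cfg[[nm]]) %||% character(0)
    }
  }
  # custom extraction lists drop the default SIR-incompatible method unless
  # the config names its own
  if (!is.null(args$extractions) && is.null(args$sir_incompatible)) {
    args$sir_incompatible <- intersect("direct_dipstick", args$extractions)
  }
  if (!is.null(cfg$controls)) args$controls <- unlist(cfg$controls)
  if (!is.null(cfg$filtration_time)) {
    args$filtration_time <- lapply(cfg$filtration_time, unlist)
  }
  do.call(design_config, args)
}

#' Write posterior summaries and draws to disk
#'
#' Summaries as CSV; draws and the pointwise log-likelihood as plain CSV
#' matrices (column headers name parameters / observation ids).
#'
#' @param fit an `edna_yield_fit`.
#' @param dir destination directory (created if needed).
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$summary, file.path(dir, "posterior_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$draws), file.path(dir, "draws.csv"),
                   row.names = FALSE)
  ll <- as.data.frame(fit$loglik)
  names(ll) <- paste0("obs_", seq_len(ncol(ll)))
  utils::write.csv(ll, file.path(dir, "loglik.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a pointwise log-likelihood matrix written by [write_fit()]
#' @param path `loglik.csv` produced by [write_fit()].
#' @export
read_loglik <- function(path) {
  as.matrix(utils::read.csv(path))
}
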