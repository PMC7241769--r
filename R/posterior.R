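# Posterior queries on fitted yield-decomposition models.

# resolve a draws matrix from a fit or a bare named matrix/vector
draws_matrix <- function(post) {
  if (inherits(post, "edna_yield_fit")) return(post$draws)
  if (is.matrix(post) && !is.null(colnames(post))) return(post)
  if (is.numeric(post) && !is.null(names(post))) {
    return(matrix(post, 1, dimnames = list(NULL, names(post))))
  }
  stop_config("expected an edna_yield_fit or a named draws matrix/vector")
}

#' Posterior ratio of two yield parameters
#'
#' Fold-change between two parameters: the ratio of posterior means, plus a
#' draw-wise ratio with its 95 percent interval. Accepts a fitted model or any
#' named draws matrix (a single named vector of means gives the
#' deterministic ratio, useful for worked examples on published means).
#'
#' @param post an `edna_yield_fit`, named draws matrix, or named numeric
#'   vector of means.
#' @param param_a,param_b column names, e.g. `"Y_f[nitrocellulose]"`.
#' @return list with `ratio_of_means`, `mean_ratio` (mean of draw-wise
#'   ratios) and `interval` (2.5/97.5 percentiles of the draw-wise ratio).
#' @export
posterior_yield_ratio <- function(post, param_a, param_b) {
  d <- draws_matrix(post)
  for (p in c(param_a, param_b)) {
    if (!p %in% colnames(d)) stop_config("parameter '%s' not in posterior", p)
  }
  a <- d[, param_a]; b <- d[, param_b]
  rr <- a / b
  list(ratio_of_means = mean(a) / mean(b),
       mean_ratio = mean(rr),
       interval = stats::quantile(rr, c(0.025, 0.975), names = FALSE))
}

#' Posterior SIR effect per filter-extraction pair
#'
#' The expected yield gained by adding secondary inhibitor removal to a
#' protocol is the inhibitor product `I_f * I_e` (capped by the available
#' yield: the realized gain cannot exceed `Y_f * Y_e`). Only the product is
#' identified by the data; its split between filter and extraction is
#' prior-dependent. Pairs whose no-SIR observations are all censored are
#' flagged: for those, SIR was essential for any amplification and the data
#' only bound the product from below.
#'
#' @param fit an `edna_yield_fit`.
#' @param observations optional `edna_yields` table used to determine the
#'   censoring flags (defaults to the data inside the fitted model).
#' @return data.frame of class `edna_sir_effect`: one row per
#'   filter-extraction pair with posterior mean/interval of the effect and a
#'   `sir_essential` flag.
#' @export
sir_effect <- function(fit, observations = NULL) {
  stopifnot(inherits(fit, "edna_yield_fit"))
  model <- fit$model
  dat <- if (is.null(observations)) {
    model$data
  } else {
    d <- as.data.frame(observations)
    if ("is_control" %in% names(d)) d <- d[!d$is_control, ]
    data.frame(filter = d$filter, extraction = d$extraction,
               sir = as.logical(d$sir), censored = as.logical(d$censored))
  }
  out <- list(); k <- 0L
  for (f in model$filters) for (e in model$extractions) {
    prod_draws <- fit$draws[, paste0("I_f[", f, "]")] *
      fit$draws[, paste0("I_e[", e, "]")]
    avail <- fit$draws[, paste0("Y_f[", f, "]")] *
      fit$draws[, paste0("Y_e[", e, "]")]
    eff <- pmin(prod_draws, avail)
    nosir <- dat$filter == f & dat$extraction == e & !dat$sir
    essential <- any(nosir) && all(dat$censored[nosir])
    k <- k + 1L
    out[[k]] <- data.frame(
      filter = f, extraction = e,
      effect_mean = mean(eff),
      effect_q2.5 = stats::quantile(eff, 0.025, names = FALSE),
      effect_q97.5 = stats::quantile(eff, 0.975, names = FALSE),
      inhibitor_product_mean = mean(prod_draws),
      n_no_sir = sum(nosir),
      sir_essential = essential)
  }
  res <- do.call(rbind, out)
  class(res) <- c("edna_sir_effect", "data.frame")
  res
}

#' Expected yield per protocol under each posterior draw
#'
#' Evaluates the fitted mean structure for every enumerated protocol and
#' draw; useful for checking that adding SIR never lowers expected yield
#' (the subtracted inhibitor term is non-negative under every draw).
#'
#' @param fit an `edna_yield_fit`.
#' @param sir logical: evaluate with or without the SIR step.
#' @return matrix draws x protocols (columns named "filter:extraction").
#' @export
posterior_expected_yield <- function(fit, sir = TRUE) {
  model <- fit$model
  S <- nrow(fit$zdraws)
  combos <- expand.grid(filter = model$filters,
                        extraction = model$extractions,
                        stringsAsFactors = FALSE)
  out <- matrix(NA_real_, S, nrow(combos),
                dimnames = list(NULL, paste(combos$filter, combos$extraction,
                                            sep = ":")))
  for (si in seq_len(S)) {
    tr <- model$transform(fit$zdraws[si, ])
    ye_eff <- pmin(pmax(
      tr$Y_e[combos$extraction] + tr$delta[cbind(combos$filter,
                                                 combos$extraction)], 0), 1)
    mu <- tr$Y_f[combos$filter] * ye_eff -
      (if (sir) 0 else tr$I_f[combos$filter] * tr$I_e[combos$extraction])
    out[si, ] <- pmax(0, mu)
  }
  out
}
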