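# Quantification: turn raw Cq tables into yield-fraction observations, and
# fit the auxiliary relationships (amplification probability vs
# concentration; yield vs input concentration).

#' Convert an experiment's Cq values to yield observations
#'
#' Technical qPCR replicates are combined as the mean of the *copy numbers*
#' of detected replicates (copy number is the linear scale of interest, so
#' averaging Cq values, which are logarithmic, would bias the estimate).
#' When every technical replicate is a non-detect the observation is left-
#' censored at the detection limit of the curve and `amplified` is FALSE;
#' censored observations never contribute a numeric yield.
#'
#' @param experiment data.frame with protocol columns
#'   (`filter`/`extraction`/`sir`), `input_copies` and `cq_*` columns, as
#'   produced by [simulate_experiment()] or read from CSV.
#' @param curve an [standard_curve()] (defaults to the one attached to a
#'   simulated experiment).
#' @return data.frame of class `edna_yields`: one row per sample with
#'   `recovered_copies`, `yield` (= recovered/input; NA when censored),
#'   `censored`, `amplified`, and `yield_limit` (detection limit expressed as
#'   a yield fraction) columns. Control samples keep `is_control = TRUE` and
#'   an NA yield when they carry no input.
#' @export
compute_yields <- function(experiment, curve = attr(experiment, "curve")) {
  if (is.null(curve)) stop_config("no standard curve supplied or attached")
  cq_cols <- grep("^cq_\\d+$", names(experiment), value = TRUE)
  if (!length(cq_cols)) stop_config("experiment has no cq_* columns")
  if (!"input_copies" %in% names(experiment)) {
    stop_config("experiment needs an input_copies column")
  }
  is_ctrl <- if ("is_control" %in% names(experiment)) experiment$is_control
             else rep(FALSE, nrow(experiment))
  if (any(experiment$input_copies[!is_ctrl] <= 0)) {
    stop_config("non-control samples must have input_copies > 0")
  }
  cqm <- as.matrix(experiment[, cq_cols, drop = FALSE])
  lod <- detection_limit(curve)
  n <- nrow(experiment)
  recovered <- numeric(n); censored <- logical(n)
  for (i in seq_len(n)) {
    det <- cqm[i, !is.na(cqm[i, ])]
    if (length(det)) {
      recovered[i] <- mean(cq_to_copies(det, curve))
    } else {
      recovered[i] <- NA_real_
      censored[i] <- TRUE
    }
  }
  input <- experiment$input_copies
  yield <- ifelse(censored | input <= 0, NA_real_, recovered / input)
  out <- data.frame(sample_id = experiment$sample_id %||%
                      sprintf("S%03d", seq_len(n)),
                    filter = experiment$filter,
                    extraction = experiment$extraction,
                    sir = experiment$sir,
                    is_control = is_ctrl,
                    input_copies = input,
                    recovered_copies = recovered,
                    yield = yield,
                    censored = censored,
                    amplified = !censored,
                    yield_limit = ifelse(input > 0, lod / input, NA_real_),
                    stringsAsFactors = FALSE)
  if ("spike_ng_per_l" %in% names(experiment)) {
    out$spike_ng_per_l <- experiment$spike_ng_per_l
  }
  class(out) <- c("edna_yields", "data.frame")
  out
}

#' Estimate average input concentration from spiked samples
#'
#' Given recovered copies per liter from samples processed with a reference
#' protocol of known average yield, the input concentration is
#' recovered / reference_yield. Returns the mean and SD over samples.
#'
#' @param recovered_per_l numeric vector of recovered copies per liter.
#' @param reference_yield the reference protocol's average yield fraction
#'   (> 0), e.g. estimated from a spike-in dilution series.
#' @return list with `mean`, `sd` and per-sample `estimates`.
#' @export
estimate_input_concentration <- function(recovered_per_l, reference_yield) {
  if (!is.numeric(reference_yield) || length(reference_yield) != 1 ||
      !is.finite(reference_yield) || reference_yield <= 0) {
    stop_config("reference_yield must be a single positive number")
  }
  est <- recovered_per_l / reference_yield
  list(mean = mean(est), sd = stats::sd(est), estimates = est)
}

#' Fit the logistic amplification-probability model
#'
#' Maximum-likelihood logistic regression of the binary amplification
#' outcome on log10 copies, with the slope constrained non-negative
#' (detection cannot get less likely as concentration rises) and a small
#' fixed ridge penalty so that perfectly separated data still yield a
#' finite, flagged fit.
#'
#' @param copies starting copy numbers (> 0).
#' @param amplified logical outcomes.
#' @param ridge ridge penalty on (a, b) (default 1e-4).
#' @return an [amplification_model()] with `separation` set when the data
#'   contain a single outcome class or are perfectly separable.
#' @export
fit_amplification_probability <- function(copies, amplified, ridge = 1e-4) {
  stopifnot(length(copies) == length(amplified))
  ok <- is.finite(copies) & copies > 0 & !is.na(amplified)
  x <- log10(copies[ok]); yv <- as.numeric(amplified[ok])
  if (!length(x)) stop_config("no usable observations")
  one_class <- length(unique(yv)) < 2
  negll <- function(par) {
    eta <- par[1] + par[2] * x
    -sum(yv * stats::plogis(eta, log.p = TRUE) +
           (1 - yv) * stats::plogis(-eta, log.p = TRUE)) +
      ridge * sum(par^2)
  }
  fit <- stats::optim(c(0, 1), negll, method = "L-BFGS-B",
                      lower = c(-Inf, 0), upper = c(Inf, Inf))
  eta <- fit$par[1] + fit$par[2] * x
  p <- stats::plogis(eta)
  separated <- one_class || all(abs(p - yv) < 1e-4)
  if (separated) {
    warning("amplification outcomes are (quasi-)separated; ",
            "returning the ridge-regularized fit", call. = FALSE)
  }
  amplification_model(a = fit$par[1], b = fit$par[2], separation = separated)
}

#' Regression of log10 yield on log10 input concentration
#'
#' Ordinary least squares of log10(yield) on log10(input), quantifying how
#' the per-protocol yield fraction changes with input concentration (a
#' mildly negative slope indicates saturation at high input).
#'
#' @param input input copy numbers or concentrations (> 0).
#' @param yield positive yield fractions.
#' @param level confidence level for the slope interval (default 0.95).
#' @return list with `slope`, `intercept`, `ci` (slope interval), `p_value`
#'   (two-sided, slope = 0), `r_squared`, and the fitted `lm` object.
#' @export
fit_concentration_yield_regression <- function(input, yield, level = 0.95) {
  stopifnot(length(input) == length(yield))
  if (any(!is.finite(input)) || any(!is.finite(yield)) ||
      any(input <= 0) || any(yield <= 0)) {
    stop_config("input and yield must be positive (log-log regression)")
  }
  if (length(input) < 3) stop_config("need >= 3 points")
  d <- data.frame(ly = log10(yield), lx = log10(input))
  fit <- stats::lm(ly ~ lx, data = d)
  sm <- quiet_summary(fit)
  slope <- unname(stats::coef(fit)[2])
  # slope p-value is NaN for an exactly-constant response; report 1
  p <- if (nrow(sm$coefficients) >= 2 && is.finite(sm$coefficients[2, 4]))
    sm$coefficients[2, 4] else 1
  ci <- withCallingHandlers(
    tryCatch(stats::confint(fit, "lx", level = level)[1, ],
             error = function(e) c(NA_real_, NA_real_)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       ci = unname(ci), p_value = p, r_squared = sm$r.squared, fit = fit)
}
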