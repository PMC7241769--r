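# qPCR standard curves: Cq is linear in log10 starting copies. The curve
# converts Cq to absolute copy number and carries the detection ceiling
# (maximum cycle count) used for censoring non-detects.

#' Construct a standard curve directly from coefficients
#'
#' @param slope Cq change per log10 copies (must be negative; -3.3219
#'   corresponds to 100 percent amplification efficiency).
#' @param intercept Cq at a single starting copy.
#' @param max_cycles cycle ceiling; Cq values above it are non-detects.
#' @param sigma_cq technical Cq noise SD (used when simulating).
#' @param r_squared optional fit R^2 (1 for a constructed curve).
#' @return An object of class `edna_standard_curve` with derived
#'   amplification `efficiency` = 10^(-1/slope) - 1.
#' @export
standard_curve <- function(slope = -3.3219, intercept = 38,
                           max_cycles = 40L, sigma_cq = 0.25,
                           r_squared = 1) {
  if (!is.finite(slope) || slope >= 0) {
    stop_config("standard-curve slope must be negative (got %s)", format(slope))
  }
  eff <- 10^(-1 / slope) - 1
  structure(list(slope = slope, intercept = intercept,
                 efficiency = eff, r_squared = r_squared,
                 sigma_cq = sigma_cq, max_cycles = as.integer(max_cycles)),
            class = "edna_standard_curve")
}

#' Fit a standard curve to a dilution ladder
#'
#' Ordinary least squares of Cq on log10 copies across a serial-dilution
#' ladder (e.g. a synthetic gBlock). All ladder points must be detected.
#'
#' @param ladder data.frame with columns `copies` (> 0) and `cq`.
#' @param max_cycles cycle ceiling attached to the fitted curve.
#' @param sigma_cq Cq noise SD attached to the curve (defaults to the
#'   residual SD of the fit when >= 3 residual df, else 0.25).
#' @return `edna_standard_curve` with slope, intercept, efficiency and R^2.
#' @export
fit_standard_curve <- function(ladder, max_cycles = 40L, sigma_cq = NULL) {
  if (!all(c("copies", "cq") %in% names(ladder))) {
    stop_config("ladder needs columns 'copies' and 'cq'")
  }
  ok <- is.finite(ladder$cq) & is.finite(ladder$copies) & ladder$copies > 0
  ladder <- ladder[ok, , drop = FALSE]
  lx <- log10(ladder$copies)
  if (length(unique(lx)) < 3) {
    stop_config("standard curve needs >= 3 distinct detected dilution levels")
  }
  fit <- stats::lm(cq ~ lx, data = data.frame(cq = ladder$cq, lx = lx))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop_config("fitted standard-curve slope is not negative; check the ladder")
  }
  r2 <- quiet_summary(fit)$r.squared
  if (is.null(sigma_cq)) {
    sigma_cq <- if (stats::df.residual(fit) >= 3) quiet_summary(fit)$sigma else 0.25
  }
  standard_curve(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 max_cycles = max_cycles, sigma_cq = sigma_cq,
                 r_squared = r2)
}

#' Convert Cq values to absolute copy numbers
#'
#' Inverts the standard curve: copies = 10^((cq - intercept) / slope).
#' Non-detects (NA) propagate as NA — a censored observation, not zero.
#'
#' @param cq numeric Cq values; NA marks a non-detect.
#' @param curve an `edna_standard_curve`.
#' @export
cq_to_copies <- function(cq, curve) {
  stopifnot(inherits(curve, "edna_standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Expected Cq for a given copy number (the noiseless curve)
#' @param copies starting copies (> 0).
#' @param curve an `edna_standard_curve`.
#' @export
copies_to_cq <- function(copies, curve) {
  stopifnot(inherits(curve, "edna_standard_curve"))
  curve$intercept + curve$slope * log10(copies)
}

#' Copy number at the detection ceiling
#'
#' The smallest copy number whose expected Cq still falls within
#' `max_cycles`; observations below it are left-censored.
#' @param curve an `edna_standard_curve`.
#' @export
detection_limit <- function(curve) {
  cq_to_copies(curve$max_cycles, curve)
}

#' @export
print.edna_standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.3f %+.4f * log10(copies)\n", x$intercept,
    x$slope))
  cat(sprintf("  efficiency %.1f%%, R^2 %.4f, ceiling %d cycles (LOD %.3g copies)\n",
              100 * x$efficiency, x$r_squared, x$max_cycles,
              detection_limit(x)))
  invisible(x)
}

#' Logistic amplification-probability model
#'
#' Probability that a reaction amplifies at all, as a logistic function of
#' log10 starting copies: p = plogis(a + b * log10(copies)). `b >= 0` so the
#' probability is non-decreasing in concentration.
#'
#' @param a log-odds intercept.
#' @param b log-odds slope per log10 copies (>= 0).
#' @param separation flag set by [fit_amplification_probability()] when the
#'   training data were perfectly separated.
#' @export
amplification_model <- function(a = -1.0, b = 2.0, separation = FALSE) {
  if (b < 0) stop_config("amplification slope b must be >= 0")
  structure(list(a = a, b = b, separation = separation),
            class = "edna_amplification_model")
}

#' Amplification probability at a copy number
#' @param copies starting copies (0 gives probability 0).
#' @param amp an `edna_amplification_model`.
#' @export
amplification_probability <- function(copies, amp) {
  stopifnot(inherits(amp, "edna_amplification_model"))
  p <- ifelse(copies > 0, stats::plogis(amp$a + amp$b * log10(pmax(copies, 1e-300))), 0)
  p
}

#' @export
print.edna_amplification_model <- function(x, ...) {
  mid <- if (x$b > 0) 10^(-x$a / x$b) else NA_real_
  cat(sprintf("Logistic amplification model: logit(p) = %.3f %+.3f * log10(copies)\n",
              x$a, x$b))
  if (is.finite(mid)) cat(sprintf("  50%% detection at %.3g copies\n", mid))
  if (isTRUE(x$separation)) cat("  note: fitted on separated data (regularized)\n")
  invisible(x)
}
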