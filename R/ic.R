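# Predictive model comparison: WAIC, Pareto-smoothed importance-sampling
# leave-one-out (PSIS-LOO), an exact refit-LOO path for small problems, and
# model weights (pseudo-BMA and stacking).

new_ic_result <- function(criterion, pointwise_elpd, p_pointwise, lppd_pointwise,
                          diagnostics = list()) {
  n <- length(pointwise_elpd)
  elpd <- sum(pointwise_elpd)
  se <- sqrt(n * stats::var(pointwise_elpd))
  structure(list(criterion = criterion,
                 elpd = elpd,
                 p_eff = sum(p_pointwise),
                 se = se,
                 lppd = sum(lppd_pointwise),
                 pointwise = data.frame(elpd = pointwise_elpd,
                                        p = p_pointwise,
                                        lppd = lppd_pointwise),
                 n_obs = n,
                 diagnostics = diagnostics),
            class = "edna_ic_result")
}

#' @export
print.edna_ic_result <- function(x, ...) {
  cat(sprintf("%s: elpd %.2f (SE %.2f), effective parameters %.2f, n = %d\n",
              toupper(x$criterion), x$elpd, x$se, x$p_eff, x$n_obs))
  if (!is.null(x$diagnostics$pareto_k)) {
    bad <- sum(x$diagnostics$pareto_k > 0.7)
    cat(sprintf("  Pareto k: max %.2f, %d observation(s) above 0.7\n",
                max(x$diagnostics$pareto_k), bad))
  }
  invisible(x)
}

check_loglik <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2 || ncol(loglik) < 1) {
    stop_config("log-likelihood matrix needs >= 2 draws and >= 1 observation")
  }
  if (any(!is.finite(loglik))) {
    stop_config("log-likelihood matrix contains non-finite entries")
  }
  loglik
}

#' Widely-applicable information criterion
#'
#' From a draws x observations pointwise log-likelihood matrix:
#' `lppd_i = log mean_d exp(ll[d, i])`, `p_i = var_d(ll[d, i])`,
#' `elpd_waic = sum(lppd_i - p_i)`, with the standard error from the
#' dispersion of per-observation contributions. The variance over draws uses
#' the 1/S normalization, matching the Monte Carlo mean in `lppd` and making
#' the criterion exactly invariant under duplication of draws.
#'
#' @param loglik numeric matrix, posterior draws in rows, observations in
#'   columns.
#' @return an `edna_ic_result`.
#' @export
compute_waic <- function(loglik) {
  loglik <- check_loglik(loglik)
  S <- nrow(loglik)
  lppd_i <- col_logsumexp(loglik) - log(S)
  p_i <- colMeans(sweep(loglik, 2, colMeans(loglik))^2)
  new_ic_result("waic", lppd_i - p_i, p_i, lppd_i)
}

# ---- generalized Pareto tail fit (Zhang & Stephens 2009 estimator) --------

# Profile-likelihood fit of a generalized Pareto distribution to positive
# exceedances x, with the weak prior on k used in PSIS practice. Returns
# shape k and scale sigma.
gpd_fit <- function(x, wip = TRUE) {
  x <- sort.int(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * xstar)
  k_of <- function(th) vapply(th, function(t) -mean(log1p(-t * x)), numeric(1))
  kj <- k_of(theta)
  lj <- n * (log(theta / kj) + kj - 1)
  w <- exp(lj - logsumexp(lj))
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  sigma <- k / theta_hat
  if (wip) k <- (n * k + 10 * 0.5) / (n + 10)  # regularize toward 0.5
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smoothed importance weights for one observation.
# lw: raw log importance ratios (one per draw). Returns smoothed log
# weights (unnormalized) and the Pareto k diagnostic.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  tail_len <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  if (tail_len < 5) return(list(lw = lw, k = -Inf))
  ord <- order(lw)
  tail_idx <- ord[seq(S - tail_len + 1L, S)]
  cutoff <- exp(lw[ord[S - tail_len]])
  exceed <- exp(lw[tail_idx]) - cutoff
  if (all(exceed <= 0) || length(unique(exceed)) < 2) {
    return(list(lw = lw, k = -Inf))
  }
  fit <- gpd_fit(exceed[exceed > 0])
  n_pos <- sum(exceed > 0)
  # replace tail weights by expected order statistics of the fitted GPD
  probs <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- cutoff + vapply(probs, gpd_quantile, numeric(1),
                              k = fit$k, sigma = fit$sigma)
  smoothed <- pmin(smoothed, exp(0))        # truncate at max raw weight (=1)
  lw[tail_idx[order(exp(lw[tail_idx]))]] <- log(smoothed)
  list(lw = lw - max(lw), k = fit$k, n_tail = n_pos)
}

#' PSIS leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density under
#' leave-one-out resampling by importance sampling with Pareto-smoothed
#' weights: for observation i the raw log ratio is `-ll[d, i]`; the largest
#' ratios are replaced by expected order statistics of a generalized Pareto
#' distribution fitted to the tail. Observations whose Pareto k exceeds
#' `k_threshold` are listed in the diagnostics — their LOO contribution is
#' unreliable and a refit ([refit_loo()]) is advised.
#'
#' @param loglik draws x observations log-likelihood matrix.
#' @param k_threshold Pareto-k flag threshold (default 0.7).
#' @return an `edna_ic_result` with `diagnostics$pareto_k` and
#'   `diagnostics$flagged`.
#' @export
compute_loo <- function(loglik, k_threshold = 0.7) {
  loglik <- check_loglik(loglik)
  S <- nrow(loglik); n <- ncol(loglik)
  lppd_i <- col_logsumexp(loglik) - log(S)
  elpd_i <- numeric(n); k_i <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-loglik[, i])
    k_i[i] <- sm$k
    lw_norm <- sm$lw - logsumexp(sm$lw)
    elpd_i[i] <- logsumexp(lw_norm + loglik[, i])
  }
  flagged <- which(k_i > k_threshold)
  new_ic_result("loo", elpd_i, lppd_i - elpd_i, lppd_i,
                diagnostics = list(pareto_k = k_i, flagged = flagged,
                                   k_threshold = k_threshold))
}

#' Exact refit leave-one-out (oracle path for small problems)
#'
#' Brute-force LOO: refit the model once per left-out observation and
#' evaluate `log E_post(-i) [ p(y_i | theta) ]` by Monte Carlo over the
#' refit's draws. Feasible only for small n; used as the independent oracle
#' against which PSIS-LOO is validated.
#'
#' @param data a list or data.frame of n observations (rows index
#'   observations when a data.frame).
#' @param fitter function(data) returning posterior draws (matrix or vector
#'   per draw) for the model fitted to `data`.
#' @param logdensity function(draws, datum) returning the log-likelihood of
#'   the single held-out observation under each draw.
#' @return an `edna_ic_result` with criterion "refit_loo" (the `p_eff` and
#'   `lppd` slots use the full-data fit obtained from `fitter(data)`).
#' @export
refit_loo <- function(data, fitter, logdensity) {
  get_row <- function(d, i) if (is.data.frame(d)) d[i, , drop = FALSE] else d[[i]]
  drop_row <- function(d, i) if (is.data.frame(d)) d[-i, , drop = FALSE] else d[-i]
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  full_draws <- fitter(data)
  lppd_i <- elpd_i <- numeric(n)
  for (i in seq_len(n)) {
    yi <- get_row(data, i)
    ll_full <- logdensity(full_draws, yi)
    lppd_i[i] <- logsumexp(ll_full) - log(length(ll_full))
    draws_i <- fitter(drop_row(data, i))
    ll_i <- logdensity(draws_i, yi)
    elpd_i[i] <- logsumexp(ll_i) - log(length(ll_i))
  }
  new_ic_result("refit_loo", elpd_i, lppd_i - elpd_i, lppd_i)
}

#' Model weights from information-criterion results
#'
#' Pseudo-BMA (Akaike-type) weights `w_m proportional to exp(elpd_m)`
#' computed on a common set of observations, and optionally stacking
#' weights, which maximize the summed log of the weighted pointwise
#' predictive densities over the probability simplex.
#'
#' @param results named list of `edna_ic_result` objects fitted to the same
#'   observations.
#' @param method "pseudobma" (default) or "stacking".
#' @return named numeric weights summing to 1.
#' @export
model_weights <- function(results, method = c("pseudobma", "stacking")) {
  method <- match.arg(method)
  if (length(results) < 2) stop_config("need >= 2 models to weight")
  ns <- vapply(results, function(r) r$n_obs, numeric(1))
  if (length(unique(ns)) != 1) {
    stop_config("all models must be scored on the same observations")
  }
  nm <- names(results) %||% paste0("model", seq_along(results))
  if (method == "pseudobma") {
    elpd <- vapply(results, function(r) r$elpd, numeric(1))
    w <- exp(elpd - max(elpd))
    w <- w / sum(w)
  } else {
    lpd <- vapply(results, function(r) r$pointwise$elpd,
                  numeric(results[[1]]$n_obs))
    # maximize sum_i log( sum_m w_m exp(lpd_im) ) over the simplex via a
    # softmax parameterization
    M <- ncol(lpd)
    obj <- function(a) {
      w <- exp(a - max(a)); w <- w / sum(w)
      -sum(apply(lpd, 1, function(r) logsumexp(r + log(w))))
    }
    opt <- stats::optim(rep(0, M), obj, method = "BFGS",
                        control = list(maxit = 500))
    w <- exp(opt$par - max(opt$par)); w <- w / sum(w)
  }
  stats::setNames(as.numeric(w), nm)
}
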