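# Bayesian decomposition of end-to-end eDNA yield into per-step fractions.
#
# Mean structure (per observation, filter f, extraction e, SIR indicator s):
#   no interference:  mu = max(0, Y_f * Y_e            - I_f * I_e * (1-s))
#   interference:     mu = max(0, Y_f * (Y_e + d[f,e]) - I_f * I_e * (1-s))
# with d[f,e] zero-sum across filters within each extraction so the
# extraction main effects stay identified.
#
# Likelihood: Normal observation noise on the yield fraction with shared SD
# sigma; non-detects contribute the left-censored mass Phi((L - mu)/sigma)
# at the detection-limit yield L.
#
# End-to-end yields only identify the *product* Y_f * Y_e: multiplying all
# filter yields by c and dividing all extraction yields by c leaves every mu
# unchanged. The model therefore carries a calibration anchor — a Gaussian
# prior on the logit capture ratio of one reference filter — that pins the
# absolute scale of the split. All ratios, rankings, SIR effects and model
# comparisons are invariant to the anchor. The same degeneracy affects
# I_f * I_e, whose split is reported but only the product is interpretable.

#' Specification of a yield-decomposition model
#'
#' @param variant `"no_interference"` (extraction yield indexed by extraction
#'   only) or `"interference"` (adds zero-sum filter-by-extraction offsets to
#'   the extraction yield).
#' @param priors list overriding any of: `anchor_level` (reference filter
#'   name; default first filter alphabetically), `anchor_mean` (its assumed
#'   capture ratio, default 0.00107), `anchor_sd` (SD on the logit scale,
#'   default 0.15), `sigma_scale` (Half-Normal scale for the observation SD;
#'   default 2 x SD of the detected yields), `delta_sd` (Normal SD of the
#'   interference offsets, default 0.05). All yield and inhibitor fractions
#'   carry flat Beta(1, 1) priors on \[0, 1\].
#' @param censoring treat non-detects as left-censored at the detection
#'   limit (default TRUE); when FALSE they enter as exact zero yields.
#' @param inference list of defaults for [fit_yield_model()]:
#'   `method` ("advi"/"mcmc"), `iterations`, `draws`, `seed`.
#' @return object of class `edna_yield_model_spec`.
#' @export
yield_model_spec <- function(variant = c("no_interference", "interference"),
                             priors = list(), censoring = TRUE,
                             inference = list()) {
  variant <- match.arg(variant)
  pri <- utils::modifyList(
    list(anchor_level = NULL, anchor_mean = 0.00107, anchor_sd = 0.15,
         sigma_scale = NULL, delta_sd = 0.05),
    priors)
  inf <- utils::modifyList(
    list(method = "advi", iterations = 3000L, draws = 2000L, seed = 1L),
    inference)
  structure(list(variant = variant, priors = pri, censoring = censoring,
                 inference = inf),
            class = "edna_yield_model_spec")
}

#' Build a yield-decomposition model from observations
#'
#' Validates the data (controls are dropped; at least two filters and two
#' extractions must remain or no contrast is identifiable), lays out the
#' unconstrained parameter vector and returns closures for the log
#' posterior, its analytic gradient and the pointwise log-likelihood.
#'
#' @param observations an `edna_yields` data.frame ([compute_yields()]), or
#'   any data.frame with `filter`, `extraction`, `sir`, `yield`, `censored`,
#'   `yield_limit` columns.
#' @param spec an [yield_model_spec()].
#' @return object of class `edna_yield_model`.
#' @export
build_yield_model <- function(observations, spec = yield_model_spec()) {
  stopifnot(inherits(spec, "edna_yield_model_spec"))
  obs <- as.data.frame(observations)
  if ("is_control" %in% names(obs)) obs <- obs[!obs$is_control, , drop = FALSE]
  need <- c("filter", "extraction", "sir", "yield", "censored", "yield_limit")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop_config("observations missing column(s): %s",
                                paste(miss, collapse = ", "))
  filters <- sort(unique(obs$filter))
  extractions <- sort(unique(obs$extraction))
  if (length(filters) < 2 || length(extractions) < 2) {
    stop_config(paste("need >= 2 filters and >= 2 extractions to identify",
                      "per-step yields (got %d and %d)"),
                length(filters), length(extractions))
  }
  Fn <- length(filters); En <- length(extractions)
  fi <- match(obs$filter, filters)
  ei <- match(obs$extraction, extractions)
  s <- as.numeric(obs$sir)           # 1 = SIR used, inhibitor term off
  cens <- as.logical(obs$censored)
  y <- obs$yield
  L <- obs$yield_limit
  if (!spec$censoring) { y[cens] <- 0; cens[] <- FALSE }
  y[cens] <- NA_real_
  if (any(!is.finite(y[!cens]))) stop_config("non-finite yields in data")
  if (any(cens & !is.finite(L))) stop_config("censored rows need a finite yield_limit")

  pri <- spec$priors
  anchor_level <- pri$anchor_level %||% filters[1]
  if (!anchor_level %in% filters) {
    stop_config("anchor_level '%s' is not an observed filter", anchor_level)
  }
  anchor_idx <- match(anchor_level, filters)
  anchor_mu <- stats::qlogis(pri$anchor_mean)
  sigma_scale <- pri$sigma_scale %||% max(2 * stats::sd(y[!cens]), 1e-8)

  interference <- spec$variant == "interference"
  # unconstrained layout: z_yf (Fn) | z_ye (En) | z_if (Fn) | z_ie (En) |
  # log_sigma | eta (En * (Fn - 1), interference only)
  i_yf <- seq_len(Fn)
  i_ye <- Fn + seq_len(En)
  i_if <- Fn + En + seq_len(Fn)
  i_ie <- 2 * Fn + En + seq_len(En)
  i_ls <- 2 * Fn + 2 * En + 1L
  n_free <- i_ls
  i_eta <- NULL
  if (interference) {
    i_eta <- i_ls + seq_len(En * (Fn - 1))
    n_free <- i_ls + En * (Fn - 1)
  }
  theta_names <- c(paste0("z_yf.", filters), paste0("z_ye.", extractions),
                   paste0("z_if.", filters), paste0("z_ie.", extractions),
                   "log_sigma",
                   if (interference)
                     paste0("eta.", rep(extractions, each = Fn - 1), ".",
                            rep(filters[-Fn], En)))

  delta_matrix <- function(theta) {
    if (!interference) return(matrix(0, Fn, En))
    eta <- matrix(theta[i_eta], Fn - 1, En)
    rbind(eta, -colSums(eta))
  }

  # shared forward pass: means and intermediates for likelihood + gradient
  forward <- function(theta) {
    yf <- stats::plogis(theta[i_yf]); ye <- stats::plogis(theta[i_ye])
    iff <- stats::plogis(theta[i_if]); ie <- stats::plogis(theta[i_ie])
    sigma <- exp(theta[i_ls])
    dmat <- delta_matrix(theta)
    ye_eff_raw <- ye[ei] + dmat[cbind(fi, ei)]
    clip <- ye_eff_raw > 0 & ye_eff_raw < 1
    ye_eff <- pmin(pmax(ye_eff_raw, 0), 1)
    t_ <- yf[fi] * ye_eff - (1 - s) * iff[fi] * ie[ei]
    act <- t_ > 0
    mu <- pmax(t_, 0)
    list(yf = yf, ye = ye, iff = iff, ie = ie, sigma = sigma,
         ye_eff = ye_eff, clip = clip, act = act, mu = mu)
  }

  pointwise <- function(theta) {
    fw <- forward(theta)
    ll <- numeric(length(y))
    det <- !cens
    ll[det] <- stats::dnorm(y[det], fw$mu[det], fw$sigma, log = TRUE)
    if (any(cens)) {
      ll[cens] <- stats::pnorm(L[cens], fw$mu[cens], fw$sigma, log.p = TRUE)
    }
    ll
  }

  log_prior <- function(theta) {
    zfrac <- theta[c(i_yf, i_ye, i_if, i_ie)]
    lp <- sum(stats::dlogis(zfrac, log = TRUE))       # Beta(1,1) via logit
    lp <- lp + stats::dnorm(theta[i_yf[anchor_idx]], anchor_mu,
                            pri$anchor_sd, log = TRUE)
    sigma <- exp(theta[i_ls])
    lp <- lp - sigma^2 / (2 * sigma_scale^2) + theta[i_ls]  # HalfNormal + Jacobian
    if (interference) {
      lp <- lp + sum(stats::dnorm(theta[i_eta], 0, pri$delta_sd, log = TRUE))
    }
    lp
  }

  log_post <- function(theta) sum(pointwise(theta)) + log_prior(theta)

  grad_log_post <- function(theta) {
    fw <- forward(theta)
    sigma <- fw$sigma
    g_mu <- numeric(length(y)); g_ls_obs <- numeric(length(y))
    det <- !cens
    r <- (y[det] - fw$mu[det]) / sigma
    g_mu[det] <- r / sigma
    g_ls_obs[det] <- r^2 - 1
    if (any(cens)) {
      u <- (L[cens] - fw$mu[cens]) / sigma
      mills <- exp(stats::dnorm(u, log = TRUE) -
                     stats::pnorm(u, log.p = TRUE))
      g_mu[cens] <- -mills / sigma
      g_ls_obs[cens] <- -mills * u
    }
    a <- as.numeric(fw$act)
    w_yf <- g_mu * a * fw$ye_eff                 # d ll / d Y_f[fi]
    w_ye <- g_mu * a * fw$yf[fi] * fw$clip       # zero where Y_e + d clipped
    w_if <- -g_mu * a * (1 - s) * fw$ie[ei]
    w_ie <- -g_mu * a * (1 - s) * fw$iff[fi]

    g <- numeric(length(theta))
    for (f in seq_len(Fn)) {
      g[i_yf[f]] <- sum(w_yf[fi == f]) * fw$yf[f] * (1 - fw$yf[f])
      g[i_if[f]] <- sum(w_if[fi == f]) * fw$iff[f] * (1 - fw$iff[f])
    }
    for (e in seq_len(En)) {
      g[i_ye[e]] <- sum(w_ye[ei == e]) * fw$ye[e] * (1 - fw$ye[e])
      g[i_ie[e]] <- sum(w_ie[ei == e]) * fw$ie[e] * (1 - fw$ie[e])
    }
    g[i_ls] <- sum(g_ls_obs)
    if (interference) {
      g_delta <- matrix(0, Fn, En)
      for (f in seq_len(Fn)) for (e in seq_len(En)) {
        idx <- fi == f & ei == e
        if (any(idx)) g_delta[f, e] <- sum(w_ye[idx])
      }
      g_eta <- g_delta[seq_len(Fn - 1), , drop = FALSE] -
        matrix(g_delta[Fn, ], Fn - 1, En, byrow = TRUE)
      g[i_eta] <- as.vector(g_eta) - theta[i_eta] / pri$delta_sd^2
    }
    # prior gradients
    zidx <- c(i_yf, i_ye, i_if, i_ie)
    g[zidx] <- g[zidx] + 1 - 2 * stats::plogis(theta[zidx])
    g[i_yf[anchor_idx]] <- g[i_yf[anchor_idx]] -
      (theta[i_yf[anchor_idx]] - anchor_mu) / pri$anchor_sd^2
    g[i_ls] <- g[i_ls] - sigma^2 / sigma_scale^2 + 1
    g
  }

  transform <- function(theta) {
    yf <- stats::plogis(theta[i_yf]); names(yf) <- filters
    ye <- stats::plogis(theta[i_ye]); names(ye) <- extractions
    iff <- stats::plogis(theta[i_if]); names(iff) <- filters
    ie <- stats::plogis(theta[i_ie]); names(ie) <- extractions
    dmat <- delta_matrix(theta)
    dimnames(dmat) <- list(filters, extractions)
    list(Y_f = yf, Y_e = ye, I_f = iff, I_e = ie,
         sigma = exp(theta[i_ls]), delta = dmat)
  }

  structure(list(
    spec = spec, filters = filters, extractions = extractions,
    data = data.frame(filter = obs$filter, extraction = obs$extraction,
                      sir = as.logical(obs$sir), y = y, censored = cens,
                      limit = L),
    fi = fi, ei = ei, s = s, cens = cens, y = y, L = L,
    anchor = list(level = anchor_level, mean = pri$anchor_mean,
                  sd = pri$anchor_sd),
    sigma_scale = sigma_scale,
    n_free = n_free, theta_names = theta_names,
    layout = list(i_yf = i_yf, i_ye = i_ye, i_if = i_if, i_ie = i_ie,
                  i_ls = i_ls, i_eta = i_eta),
    log_post = log_post, grad = grad_log_post, pointwise = pointwise,
    transform = transform),
    class = "edna_yield_model")
}

#' Parameter count of a yield model
#'
#' @param model an `edna_yield_model`.
#' @param free when TRUE, count free (unconstrained) coordinates — the
#'   zero-sum constraint removes one offset per extraction; when FALSE
#'   (default), count model parameters as written: per-filter and per-method
#'   yields and carryovers, the observation SD, and (interference variant)
#'   one offset per filter-extraction cell.
#' @export
n_parameters <- function(model, free = FALSE) {
  Fn <- length(model$filters); En <- length(model$extractions)
  base <- 2 * Fn + 2 * En + 1
  if (model$spec$variant == "no_interference") return(base)
  if (free) base + En * (Fn - 1) else base + Fn * En
}

#' @export
print.edna_yield_model <- function(x, ...) {
  cat(sprintf("Yield-decomposition model (%s variant)\n", x$spec$variant))
  cat(sprintf("  %d observations (%d censored), %d filters x %d extractions\n",
              nrow(x$data), sum(x$cens), length(x$filters),
              length(x$extractions)))
  cat(sprintf("  %d parameters (%d free); scale anchor: Y_f[%s] ~ %.3g\n",
              n_parameters(x), x$n_free, x$anchor$level, x$anchor$mean))
  invisible(x)
}
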