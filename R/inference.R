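# Posterior approximation for yield-decomposition models.
#
# Default path: MAP optimization (L-BFGS-B with the analytic gradient), a
# Laplace approximation from a finite-difference Hessian of that gradient,
# then automatic-differentiation variational inference (full-rank Gaussian
# by default) refined with Adam on the reparameterized ELBO. An adaptive
# random-walk Metropolis sampler is available as a cross-check on the
# variational approximation.

# data-informed starting point on the unconstrained scale
map_init <- function(model) {
  lay <- model$layout
  theta <- numeric(model$n_free)
  anchor_mu <- stats::qlogis(model$anchor$mean)
  theta[lay$i_yf] <- anchor_mu
  det <- !model$cens
  prod_by_e <- vapply(seq_along(model$extractions), function(e) {
    idx <- det & model$ei == e & model$s == 1
    if (!any(idx)) idx <- det & model$ei == e
    if (!any(idx)) return(model$anchor$mean * 0.2)
    mean(pmax(model$y[idx], 1e-12))
  }, numeric(1))
  ye0 <- pmin(pmax(prod_by_e / model$anchor$mean, 1e-4), 0.99)
  theta[lay$i_ye] <- stats::qlogis(ye0)
  theta[lay$i_if] <- stats::qlogis(0.02)
  theta[lay$i_ie] <- stats::qlogis(0.02)
  s0 <- if (any(det)) max(stats::sd(model$y[det]) / 3, 1e-9) else 1e-6
  theta[lay$i_ls] <- log(s0)
  theta
}

map_fit <- function(model, n_restarts = 2L, seed = 1L) {
  best <- NULL
  with_seed(seed, {
    init0 <- map_init(model)
    for (r in seq_len(n_restarts)) {
      init <- if (r == 1) init0 else init0 + stats::rnorm(length(init0), 0, 0.3)
      opt <- try(stats::optim(init, fn = model$log_post, gr = model$grad,
                              method = "L-BFGS-B",
                              lower = rep(-25, model$n_free),
                              upper = rep(15, model$n_free),
                              control = list(fnscale = -1, maxit = 500)),
                 silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (is.null(best) || opt$value > best$value) best <- opt
    }
  })
  if (is.null(best)) stop_config("MAP optimization failed from all starts")
  best
}

# central finite-difference Hessian of the analytic gradient
numeric_hessian <- function(grad_fun, theta, h = 1e-4) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (grad_fun(tp) - grad_fun(tm)) / (2 * h)
  }
  (H + t(H)) / 2
}

# Cholesky factor of an approximate posterior covariance from the MAP
# Hessian, regularized so flat directions (e.g. fully-censored cells) get a
# finite, prior-scale variance.
laplace_chol <- function(model, theta_map, max_sd = 2.5) {
  H <- numeric_hessian(model$grad, theta_map)
  ev <- eigen(-H, symmetric = TRUE)
  lam <- pmax(ev$values, 1 / max_sd^2)
  cov <- ev$vectors %*% diag(1 / lam, length(lam)) %*% t(ev$vectors)
  t(chol(cov + diag(1e-10, nrow(cov))))
}

# ---- ADVI -----------------------------------------------------------------

# Maximizes the ELBO of a Gaussian q (full-rank or mean-field) over the
# unconstrained parameters using the reparameterization gradient and Adam.
run_advi <- function(model, init_mu, init_L,
                     iterations = 3000L, mc_samples = 4L,
                     learning_rate = 0.02, seed = 1L,
                     method = c("fullrank", "meanfield")) {
  method <- match.arg(method)
  p <- length(init_mu)
  mu <- init_mu
  if (method == "meanfield") {
    dvec <- log(pmax(diag(init_L), 1e-6))
    Loff <- NULL
  } else {
    dvec <- log(pmax(diag(init_L), 1e-6))
    Loff <- init_L
    Loff[upper.tri(Loff, diag = TRUE)] <- 0
  }
  low <- which(lower.tri(matrix(0, p, p)))
  npar <- p + p + if (method == "fullrank") length(low) else 0
  adam_m <- numeric(npar); adam_v <- numeric(npar)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  elbo_trace <- numeric(0)

  pack <- function() c(mu, dvec, if (method == "fullrank") Loff[low])
  unpack <- function(v) {
    mu <<- v[seq_len(p)]
    dvec <<- v[p + seq_len(p)]
    if (method == "fullrank") Loff[low] <<- v[2 * p + seq_along(low)]
  }

  with_seed(seed, {
    v <- pack()
    for (it in seq_len(iterations)) {
      unpack(v)
      Ld <- exp(dvec)
      g_mu <- numeric(p); g_d <- numeric(p)
      g_off <- if (method == "fullrank") numeric(length(low)) else NULL
      elbo <- 0
      for (m in seq_len(mc_samples)) {
        epsv <- stats::rnorm(p)
        if (method == "fullrank") {
          theta <- mu + Loff %*% epsv + Ld * epsv
          theta <- as.vector(theta)
        } else {
          theta <- mu + Ld * epsv
        }
        g <- model$grad(theta)
        elbo <- elbo + model$log_post(theta)
        g_mu <- g_mu + g
        g_d <- g_d + g * epsv * Ld
        if (method == "fullrank") {
          gl <- tcrossprod(g, epsv)
          g_off <- g_off + gl[low]
        }
      }
      g_mu <- g_mu / mc_samples
      g_d <- g_d / mc_samples + 1          # entropy: d sum(log Ld) / d dvec
      if (method == "fullrank") g_off <- g_off / mc_samples
      elbo <- elbo / mc_samples + sum(dvec) + 0.5 * p * log(2 * pi * exp(1))
      elbo_trace <- c(elbo_trace, elbo)

      grad_all <- c(g_mu, g_d, g_off)
      # a divergent step can send the log-posterior to -Inf; drop such
      # gradients and keep the state bounded so the run stays finite and
      # the convergence diagnostic can report the failure
      grad_all[!is.finite(grad_all)] <- 0
      adam_m <- b1 * adam_m + (1 - b1) * grad_all
      adam_v <- b2 * adam_v + (1 - b2) * grad_all^2
      mh <- adam_m / (1 - b1^it); vh <- adam_v / (1 - b2^it)
      lr <- learning_rate / (1 + it / iterations)
      v <- pmin(pmax(v + lr * mh / (sqrt(vh) + eps), -35), 35)
    }
    unpack(v)
  })

  Lfull <- if (method == "fullrank") {
    Lm <- Loff; diag(Lm) <- exp(dvec); Lm
  } else {
    diag(exp(dvec), p)
  }
  # convergence heuristic: relative ELBO drift over the last two deciles
  n_it <- length(elbo_trace)
  tail1 <- mean(elbo_trace[seq(max(1, n_it - n_it %/% 5), n_it)])
  tail2 <- mean(elbo_trace[seq(max(1, n_it - 2 * (n_it %/% 5)),
                               max(1, n_it - n_it %/% 5))])
  drift <- abs(tail1 - tail2) / (abs(tail1) + 1e-12)
  list(mu = mu, L = Lfull, elbo = elbo_trace,
       converged = is.finite(drift) && drift < 0.01, drift = drift)
}

advi_draws <- function(adv, n_draws, seed) {
  p <- length(adv$mu)
  with_seed(seed + 1L, {
    eps <- matrix(stats::rnorm(p * n_draws), p, n_draws)
    t(adv$mu + adv$L %*% eps)
  })
}

# ---- adaptive Metropolis ---------------------------------------------------

run_adaptive_mh <- function(model, init, init_cov, iterations = 20000L,
                            warmup = iterations %/% 2, seed = 1L) {
  p <- length(init)
  log_scale <- log(2.38 / sqrt(p))
  chol_prop <- t(chol(init_cov + diag(1e-10, p)))
  theta <- init
  lp <- model$log_post(theta)
  out <- matrix(NA_real_, iterations - warmup, p)
  acc <- 0L
  mean_run <- theta; cov_run <- init_cov
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      prop <- theta + exp(log_scale) *
        as.vector(chol_prop %*% stats::rnorm(p))
      lp_prop <- model$log_post(prop)
      a_prob <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp)) else 0
      if (stats::runif(1) < a_prob) {
        theta <- prop; lp <- lp_prop
        if (it > warmup) acc <- acc + 1L
      }
      # warmup adaptation: Haario running covariance + Robbins-Monro scale
      # tuning toward the 0.234 random-walk optimum
      w <- 1 / (it + 1)
      dev <- theta - mean_run
      mean_run <- mean_run + w * dev
      cov_run <- cov_run + w * (tcrossprod(dev) - cov_run)
      if (it <= warmup) {
        log_scale <- log_scale + 2 * it^-0.6 * (a_prob - 0.234)
        if (it %% 200 == 0 && it > 500) {
          chol_prop <- t(chol(cov_run + diag(1e-10, p)))
        }
      }
      if (it > warmup) out[it - warmup, ] <- theta
    }
  })
  list(draws = out, accept_rate = acc / (iterations - warmup))
}

#' Fit a yield-decomposition model
#'
#' Approximates the posterior of a built model. The default is variational
#' inference (`"advi"`): a MAP + Laplace initialization followed by Adam
#' optimization of the reparameterized ELBO for a full-rank Gaussian on the
#' unconstrained scale (a mean-field factorization is available but
#' understates the strong scale correlations this model induces). `"mcmc"`
#' runs adaptive random-walk Metropolis from the same initialization as an
#' independent check on the variational approximation.
#'
#' @param model an [build_yield_model()] result.
#' @param method "advi" (default) or "mcmc".
#' @param iterations optimizer iterations (ADVI) or sampler iterations
#'   (MCMC; half are warmup). Defaults come from the model spec.
#' @param draws posterior draws to return (default 2000).
#' @param seed integer seed controlling every stochastic step.
#' @param advi_variant "fullrank" (default) or "meanfield".
#' @param mc_samples Monte Carlo samples per ELBO gradient (default 4).
#' @param learning_rate Adam step size for the ELBO optimizer (default
#'   0.02; decays over the run).
#' @return object of class `edna_yield_fit`: `draws` (matrix of constrained
#'   parameter draws), `summary` (mean/SD/95 percent interval per parameter),
#'   `loglik` (draws x observations pointwise log-likelihood),
#'   `diagnostics`, and the `model`.
#' @export
fit_yield_model <- function(model,
                            method = model$spec$inference$method,
                            iterations = NULL,
                            draws = model$spec$inference$draws,
                            seed = model$spec$inference$seed,
                            advi_variant = c("fullrank", "meanfield"),
                            mc_samples = 4L, learning_rate = 0.02) {
  stopifnot(inherits(model, "edna_yield_model"))
  method <- match.arg(method, c("advi", "mcmc"))
  advi_variant <- match.arg(advi_variant)
  seed <- as.integer(seed)

  opt <- map_fit(model, seed = seed)
  Lap <- laplace_chol(model, opt$par)

  diagnostics <- list(method = method, map_logpost = opt$value)
  if (method == "advi") {
    iterations <- iterations %||% model$spec$inference$iterations
    adv <- run_advi(model, opt$par, Lap, iterations = iterations,
                    mc_samples = mc_samples, seed = seed,
                    learning_rate = learning_rate, method = advi_variant)
    zdraws <- advi_draws(adv, draws, seed)
    diagnostics$elbo <- adv$elbo
    diagnostics$converged <- adv$converged
    if (!adv$converged) {
      warning(sprintf(
        "ADVI may not have converged (relative ELBO drift %.3g); ",
        adv$drift), "inspect diagnostics$elbo", call. = FALSE)
    }
  } else {
    iterations <- iterations %||% 20000L
    cov0 <- Lap %*% t(Lap)
    mh <- run_adaptive_mh(model, opt$par, cov0, iterations = iterations,
                          seed = seed)
    keep <- round(seq(1, nrow(mh$draws), length.out = min(draws, nrow(mh$draws))))
    zdraws <- mh$draws[keep, , drop = FALSE]
    diagnostics$accept_rate <- mh$accept_rate
    diagnostics$converged <- mh$accept_rate > 0.05 && mh$accept_rate < 0.7
    if (!diagnostics$converged) {
      warning(sprintf("MCMC acceptance rate %.2f outside (0.05, 0.7); ",
                      mh$accept_rate), "treat posterior with caution",
              call. = FALSE)
    }
  }
  build_fit(model, zdraws, diagnostics)
}

# assemble the user-facing fit object from unconstrained draws
build_fit <- function(model, zdraws, diagnostics) {
  S <- nrow(zdraws)
  first <- model$transform(zdraws[1, ])
  par_names <- c(paste0("Y_f[", model$filters, "]"),
                 paste0("Y_e[", model$extractions, "]"),
                 paste0("I_f[", model$filters, "]"),
                 paste0("I_e[", model$extractions, "]"),
                 "sigma")
  if (model$spec$variant == "interference") {
    par_names <- c(par_names,
                   paste0("delta[", rep(model$filters,
                                        length(model$extractions)), ",",
                          rep(model$extractions,
                              each = length(model$filters)), "]"))
  }
  draws <- matrix(NA_real_, S, length(par_names),
                  dimnames = list(NULL, par_names))
  loglik <- matrix(NA_real_, S, nrow(model$data))
  for (si in seq_len(S)) {
    tr <- model$transform(zdraws[si, ])
    row <- c(tr$Y_f, tr$Y_e, tr$I_f, tr$I_e, tr$sigma)
    if (model$spec$variant == "interference") row <- c(row, as.vector(tr$delta))
    draws[si, ] <- row
    loglik[si, ] <- model$pointwise(zdraws[si, ])
  }
  qs <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975)))
  summary <- data.frame(parameter = par_names,
                        mean = colMeans(draws),
                        sd = apply(draws, 2, stats::sd),
                        q2.5 = qs[, 1], q97.5 = qs[, 2],
                        row.names = NULL)
  structure(list(draws = draws, zdraws = zdraws, summary = summary,
                 loglik = loglik, diagnostics = diagnostics, model = model),
            class = "edna_yield_fit")
}

#' @export
print.edna_yield_fit <- function(x, ...) {
  cat(sprintf("Yield-decomposition fit (%s, %s variant): %d draws\n",
              x$diagnostics$method, x$model$spec$variant, nrow(x$draws)))
  main <- x$summary[!grepl("^delta", x$summary$parameter), ]
  print(format(main, digits = 3), row.names = FALSE)
  invisible(x)
}
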