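# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log(sum(exp(x)))
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Column-wise logsumexp of a matrix
#' @keywords internal
col_logsumexp <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(sweep(m, 2, mx))))
}

# Deterministic derivation of a per-unit RNG seed from a root seed and an
# integer index, so each sample owns an independent stream regardless of the
# order in which samples are generated. Arithmetic stays below 2^53 so the
# modulo is exact in doubles; the result fits a 32-bit integer.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  h <- (s * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  # one extra mixing round to decorrelate adjacent indices
  h <- (h * 69621 + 7919) %% 2147483647
  as.integer(h)
}

# Evaluate a thunk with a temporary RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# summary.lm warns on noiseless data ("essentially perfect fit"); exact
# fixtures are legitimate inputs here, so that one warning is muffled
quiet_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

check_fraction <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config("%s must lie in [0, 1]; offending values: %s",
                what, paste(format(x[!is.finite(x) | x < 0 | x > 1]),
                            collapse = ", "))
  }
  invisible(x)
}

# Lognormal parameterized by mean and coefficient of variation; cv = 0
# degenerates to the mean.
rlnorm_cv <- function(n, mean, cv) {
  if (cv <= 0 || mean <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}
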