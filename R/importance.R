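# Which protocol step drives total-yield variance? A small bagged-tree
# (random forest) regressor on one-hot-encoded step factors, reporting both
# impurity-based and out-of-bag permutation importance. Implemented here
# because only the three categorical design factors are ever used as
# features, so exhaustive binary splits on one-hot columns cover the full
# CART search space.

# ---- regression trees on binary (0/1) feature matrices --------------------

build_tree <- function(X, y, mtry, min_node = 5L, max_depth = 8L) {
  nodes <- list()
  imp <- numeric(ncol(X))          # impurity (SSE-decrease) accumulator
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- list()
    length(nodes)
  }
  grow <- function(idx, depth) {
    id <- new_node()
    yy <- y[idx]
    node <- list(value = mean(yy), feature = NA_integer_,
                 left = NA_integer_, right = NA_integer_)
    if (length(idx) >= min_node && depth < max_depth &&
        stats::var(yy) > 0) {
      feats <- sample.int(ncol(X), min(mtry, ncol(X)))
      sse_parent <- sum((yy - mean(yy))^2)
      best <- list(gain = 1e-12, feature = NA_integer_)
      for (j in feats) {
        xl <- X[idx, j] == 0
        nl <- sum(xl); nr <- length(idx) - nl
        if (nl == 0 || nr == 0) next
        yl <- yy[xl]; yr <- yy[!xl]
        gain <- sse_parent - (sum((yl - mean(yl))^2) +
                                sum((yr - mean(yr))^2))
        if (gain > best$gain) best <- list(gain = gain, feature = j)
      }
      if (!is.na(best$feature)) {
        j <- best$feature
        imp[j] <<- imp[j] + best$gain
        xl <- X[idx, j] == 0
        node$feature <- j
        node$left <- grow(idx[xl], depth + 1L)
        node$right <- grow(idx[!xl], depth + 1L)
      }
    }
    nodes[[id]] <<- node
    id
  }
  root <- grow(seq_len(nrow(X)), 0L)
  list(nodes = nodes, root = root, importance = imp)
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    id <- tree$root
    repeat {
      node <- tree$nodes[[id]]
      if (is.na(node$feature)) { out[i] <- node$value; break }
      id <- if (X[i, node$feature] == 0) node$left else node$right
    }
  }
  out
}

# ---- step importance -------------------------------------------------------

one_hot <- function(f) {
  f <- as.factor(f)
  m <- stats::model.matrix(~ f - 1)
  colnames(m) <- levels(f)
  m
}

#' Random-forest importance of each protocol step
#'
#' Regresses total yield on the three design factors (filter, extraction,
#' SIR) with a bagged ensemble of regression trees on one-hot features, and
#' reports per-factor importance two ways: impurity (total SSE decrease
#' attributable to the factor's columns, normalized to sum to 1) and
#' out-of-bag permutation importance (increase in OOB MSE when the factor's
#' columns are permuted jointly), with a resampling interval across trees.
#' Permutation importance is the headline number — impurity importance is
#' biased toward high-cardinality factors. Censored observations enter as
#' zero yield.
#'
#' @param yields an `edna_yields` data.frame (controls are dropped).
#' @param seed integer seed (identical seeds give identical importances).
#' @param num_trees number of trees (default 500).
#' @param mtry features sampled per split (default 3).
#' @param min_node minimum node size (default 5).
#' @param max_depth maximum tree depth (default 8).
#' @return data.frame of class `edna_step_importance` with one row per
#'   factor: `permutation`, `permutation_q2.5`, `permutation_q97.5`,
#'   `impurity` (share), ordered by permutation importance.
#' @export
step_importance <- function(yields, seed = 1L, num_trees = 500L, mtry = 3L,
                            min_node = 5L, max_depth = 8L) {
  d <- as.data.frame(yields)
  if ("is_control" %in% names(d)) d <- d[!d$is_control, ]
  for (v in c("filter", "extraction", "sir", "yield")) {
    if (!v %in% names(d)) stop_config("yields missing column '%s'", v)
  }
  y <- ifelse(is.na(d$yield), 0, d$yield)
  groups <- list(filter = one_hot(d$filter),
                 extraction = one_hot(d$extraction),
                 sir = one_hot(d$sir))
  for (g in names(groups)) {
    if (ncol(groups[[g]]) < 2) stop_config("factor '%s' has < 2 levels", g)
  }
  X <- do.call(cbind, groups)
  gidx <- rep(names(groups), vapply(groups, ncol, integer(1)))
  n <- nrow(X)

  imp_impurity <- numeric(ncol(X))
  perm_per_tree <- matrix(NA_real_, num_trees, length(groups),
                          dimnames = list(NULL, names(groups)))
  with_seed(seed, {
    for (b in seq_len(num_trees)) {
      boot <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(boot))
      tree <- build_tree(X[boot, , drop = FALSE], y[boot], mtry,
                         min_node, max_depth)
      imp_impurity <- imp_impurity + tree$importance
      if (length(oob) >= 3) {
        base_mse <- mean((y[oob] - predict_tree(tree, X[oob, , drop = FALSE]))^2)
        for (gi in seq_along(groups)) {
          cols <- which(gidx == names(groups)[gi])
          Xp <- X[oob, , drop = FALSE]
          perm <- sample.int(length(oob))
          Xp[, cols] <- Xp[perm, cols, drop = FALSE]
          mse <- mean((y[oob] - predict_tree(tree, Xp))^2)
          perm_per_tree[b, gi] <- mse - base_mse
        }
      }
    }
  })
  perm_mean <- colMeans(perm_per_tree, na.rm = TRUE)
  qs <- apply(perm_per_tree, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  impurity_group <- vapply(names(groups), function(g) {
    sum(imp_impurity[gidx == g])
  }, numeric(1))
  tot <- sum(impurity_group)
  out <- data.frame(factor = names(groups),
                    permutation = pmax(perm_mean, 0),
                    permutation_q2.5 = qs[1, ],
                    permutation_q97.5 = qs[2, ],
                    impurity = if (tot > 0) impurity_group / tot
                               else rep(0, length(groups)),
                    row.names = NULL)
  out <- out[order(-out$permutation), ]
  rownames(out) <- NULL
  class(out) <- c("edna_step_importance", "data.frame")
  out
}

#' Ranking stability of one step's methods across the other step's strata
#'
#' For each extraction method, ranks the filters by mean observed yield
#' (censored observations count as zero), and reports whether that ordering
#' is identical in every stratum; the dual check ranks extractions within
#' each filter. Strata containing a fully-censored cell are flagged and
#' excluded from the stability verdict, since their ordering reflects
#' missingness rather than yield.
#'
#' @param yields an `edna_yields` data.frame.
#' @return list of class `edna_rank_check`: `filter_rankings` /
#'   `extraction_rankings` (one ranking per stratum), `filters_stable` /
#'   `extractions_stable`, and `flagged_strata`.
#' @export
rank_independence_check <- function(yields) {
  d <- as.data.frame(yields)
  if ("is_control" %in% names(d)) d <- d[!d$is_control, ]
  d$y0 <- ifelse(is.na(d$yield), 0, d$yield)
  filters <- sort(unique(d$filter)); extractions <- sort(unique(d$extraction))

  cell_mean <- function(f, e) mean(d$y0[d$filter == f & d$extraction == e])
  # a cell is "censoring-compromised" when one of its SIR arms (or the whole
  # cell, absent a sir column) never amplified
  cell_all_censored <- function(f, e) {
    idx <- d$filter == f & d$extraction == e
    if (!any(idx)) return(FALSE)
    if (!"sir" %in% names(d)) return(all(d$censored[idx]))
    arms <- split(d$censored[idx], d$sir[idx])
    any(vapply(arms, function(a) length(a) > 0 && all(a), logical(1)))
  }

  filter_rankings <- list(); flagged <- character(0)
  for (e in extractions) {
    means <- vapply(filters, cell_mean, numeric(1), e = e)
    if (any(vapply(filters, cell_all_censored, logical(1), e = e))) {
      flagged <- c(flagged, paste0("extraction:", e))
    }
    filter_rankings[[e]] <- filters[order(-means)]
  }
  extraction_rankings <- list()
  for (f in filters) {
    means <- vapply(extractions, function(e) cell_mean(f, e), numeric(1))
    if (any(vapply(extractions, function(e) cell_all_censored(f, e),
                   logical(1)))) {
      flagged <- c(flagged, paste0("filter:", f))
    }
    extraction_rankings[[f]] <- extractions[order(-means)]
  }
  stable_among <- function(rankings, flagged_keys, prefix) {
    keep <- setdiff(names(rankings), sub(paste0("^", prefix, ":"), "",
                                         grep(paste0("^", prefix, ":"),
                                              flagged_keys, value = TRUE)))
    if (length(keep) <= 1) return(TRUE)
    ref <- rankings[[keep[1]]]
    all(vapply(keep[-1], function(k) identical(rankings[[k]], ref),
               logical(1)))
  }
  structure(list(
    filter_rankings = filter_rankings,
    extraction_rankings = extraction_rankings,
    filters_stable = stable_among(filter_rankings, flagged, "extraction"),
    extractions_stable = stable_among(extraction_rankings, flagged, "filter"),
    flagged_strata = unique(flagged)),
    class = "edna_rank_check")
}

#' @export
print.edna_rank_check <- function(x, ...) {
  cat("Ranking-independence check\n")
  cat(sprintf("  filter ranking stable across extractions: %s\n",
              x$filters_stable))
  cat(sprintf("  extraction ranking stable across filters: %s\n",
              x$extractions_stable))
  if (length(x$flagged_strata)) {
    cat("  flagged (fully censored cells):",
        paste(x$flagged_strata, collapse = ", "), "\n")
  }
  invisible(x)
}
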