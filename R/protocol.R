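# Protocol enumeration, cost/time/yield scoring and rule-based
# recommendation. Per-sample time for a batched step is batch_time /
# batch_size; unattended incubations are excluded from batch times because
# they require no labor.

# Internal: full factorial of filter x extraction x SIR minus the SIR arm of
# SIR-incompatible extractions, in deterministic (filter, extraction, sir)
# order.
enumerate_protocol_grid <- function(filters, extractions, sir_incompatible) {
  rows <- list()
  k <- 0L
  for (f in filters) {
    for (e in extractions) {
      sir_levels <- if (e %in% sir_incompatible) FALSE else c(FALSE, TRUE)
      for (s in sir_levels) {
        k <- k + 1L
        rows[[k]] <- data.frame(filter = f, extraction = e, sir = s,
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default step catalog
#'
#' One row per method with its step kind, cost per sample, hands-on batch
#' time, batch size, mean yield (or inhibitor-carryover) attributes and SIR
#' compatibility. Yield and inhibitor columns default to published
#' per-method posterior means; costs and most batch times are editable
#' defaults (catalog numbers are meant to be replaced with a lab's own
#' figures), anchored where in-text numbers exist: the silica-column
#' extraction processes 18 samples in 77 minutes, and filtration batch times
#' are the measured per-filter means with 4 samples filtered in parallel.
#'
#' @return data.frame of class `edna_step_catalog` with columns `method`,
#'   `kind` ("filtration", "extraction" or "sir"), `cost`, `batch_time_min`,
#'   `batch_size`, `mean_yield`, `inhibitor`, `sir_compatible`.
#' @export
default_step_catalog <- function() {
  cat <- rbind(
    data.frame(method = "glass",          kind = "filtration", cost = 0.50,
               batch_time_min = 2.32,  batch_size = 4L,  mean_yield = 0.00107,
               inhibitor = 0.008, sir_compatible = TRUE),
    data.frame(method = "nitrocellulose", kind = "filtration", cost = 1.00,
               batch_time_min = 14.16, batch_size = 4L,  mean_yield = 0.00172,
               inhibitor = 0.025, sir_compatible = TRUE),
    data.frame(method = "whatman",        kind = "filtration", cost = 0.10,
               batch_time_min = 6.72,  batch_size = 4L,  mean_yield = 0.00045,
               inhibitor = 0.010, sir_compatible = TRUE),
    data.frame(method = "qiagen",         kind = "extraction", cost = 3.50,
               batch_time_min = 77,    batch_size = 18L, mean_yield = 0.475,
               inhibitor = 0.004, sir_compatible = TRUE),
    data.frame(method = "beads",          kind = "extraction", cost = 2.00,
               batch_time_min = 30,    batch_size = 24L, mean_yield = 0.206,
               inhibitor = 0.004, sir_compatible = TRUE),
    data.frame(method = "naoh",           kind = "extraction", cost = 0.15,
               batch_time_min = 45,    batch_size = 24L, mean_yield = 0.287,
               inhibitor = 0.080, sir_compatible = TRUE),
    data.frame(method = "dipstick",       kind = "extraction", cost = 0.05,
               batch_time_min = 5,     batch_size = 8L,  mean_yield = 0.047,
               inhibitor = 0.002, sir_compatible = TRUE),
    data.frame(method = "direct_dipstick", kind = "extraction", cost = 0.05,
               batch_time_min = 2,     batch_size = 8L,  mean_yield = 0.132,
               inhibitor = 0.004, sir_compatible = FALSE),
    data.frame(method = "sir",            kind = "sir",        cost = 2.00,
               batch_time_min = 12,    batch_size = 12L, mean_yield = 1.0,
               inhibitor = 0, sir_compatible = NA)
  )
  validate_step_catalog(cat)
  class(cat) <- c("edna_step_catalog", "data.frame")
  cat
}

validate_step_catalog <- function(cat) {
  need <- c("method", "kind", "cost", "batch_time_min", "batch_size",
            "mean_yield", "inhibitor", "sir_compatible")
  miss <- setdiff(need, names(cat))
  if (length(miss)) stop_config("step catalog missing column(s): %s",
                                paste(miss, collapse = ", "))
  if (any(cat$cost < 0)) stop_config("catalog costs must be >= 0")
  if (any(cat$batch_time_min <= 0)) stop_config("batch times must be > 0")
  if (any(cat$batch_size < 1)) stop_config("batch sizes must be >= 1")
  if (!all(c("filtration", "extraction") %in% cat$kind)) {
    stop_config("catalog needs at least one filtration and one extraction method")
  }
  invisible(cat)
}

#' Read a step catalog from CSV
#' @param path CSV file with the [default_step_catalog()] schema.
#' @export
read_step_catalog <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  cat$sir_compatible <- as.logical(cat$sir_compatible)
  validate_step_catalog(cat)
  class(cat) <- c("edna_step_catalog", "data.frame")
  cat
}

#' Enumerate valid protocols from a step catalog
#'
#' Full factorial of filtration x extraction x \{SIR, no SIR\}, excluding the
#' SIR arm after SIR-incompatible extractions (extractions that feed the
#' reaction directly never see the cleanup column). Deterministic
#' (filter, extraction, sir) order, duplicate-free. With 3 filters, 5
#' extractions and one SIR-incompatible extraction: 3 x (4 x 2 + 1) = 27.
#'
#' @param catalog an `edna_step_catalog`.
#' @return data.frame with columns `filter`, `extraction`, `sir`.
#' @export
enumerate_protocols <- function(catalog = default_step_catalog()) {
  validate_step_catalog(catalog)
  filters <- catalog$method[catalog$kind == "filtration"]
  extractions <- catalog$method[catalog$kind == "extraction"]
  incompat <- catalog$method[catalog$kind == "extraction" &
                               !catalog$sir_compatible]
  has_sir <- any(catalog$kind == "sir")
  if (!has_sir) incompat <- extractions
  enumerate_protocol_grid(filters, extractions, incompat)
}

#' Score protocols by expected yield, detection probability, cost and time
#'
#' Expected total yield uses the step decomposition with catalog means:
#' `max(0, Y_f * Y_e - I_f * I_e * [no SIR])`. Detection probability is the
#' amplification probability at `reference_input * yield * reaction_fraction`
#' copies. Cost is the sum of per-sample step costs; time per sample is the
#' sum of `batch_time / batch_size` over the protocol's steps. Protocols are
#' ranked by yield (descending), ties broken by time then cost.
#'
#' @param protocols data.frame from [enumerate_protocols()].
#' @param catalog an `edna_step_catalog`.
#' @param amp an [amplification_model()] for detection probability.
#' @param reference_input reference input concentration (copies per sample).
#' @param reaction_fraction fraction of the recovered extract loaded into one
#'   reaction (default 1).
#' @return data.frame of class `edna_protocol_scores`.
#' @export
score_protocols <- function(protocols = enumerate_protocols(catalog),
                            catalog = default_step_catalog(),
                            amp = amplification_model(),
                            reference_input = 1e6,
                            reaction_fraction = 1) {
  validate_step_catalog(catalog)
  row_of <- function(m) {
    i <- match(m, catalog$method)
    if (is.na(i)) stop_config("method '%s' not present in catalog", m)
    catalog[i, ]
  }
  sir_row <- if (any(catalog$kind == "sir"))
    catalog[catalog$kind == "sir", ][1, ] else NULL
  n <- nrow(protocols)
  yield <- cost <- time <- pdet <- numeric(n)
  for (i in seq_len(n)) {
    fr <- row_of(protocols$filter[i])
    er <- row_of(protocols$extraction[i])
    s <- protocols$sir[i]
    if (s && is.null(sir_row)) stop_config("catalog has no SIR step")
    y <- fr$mean_yield * er$mean_yield -
      (if (s) 0 else fr$inhibitor * er$inhibitor)
    if (s) y <- y * sir_row$mean_yield
    yield[i] <- max(0, y)
    cost[i] <- fr$cost + er$cost + if (s) sir_row$cost else 0
    time[i] <- fr$batch_time_min / fr$batch_size +
      er$batch_time_min / er$batch_size +
      if (s) sir_row$batch_time_min / sir_row$batch_size else 0
    pdet[i] <- amplification_probability(
      reference_input * yield[i] * reaction_fraction, amp)
  }
  out <- cbind(protocols,
               data.frame(expected_yield = yield,
                          detection_probability = pdet,
                          cost_per_sample = cost,
                          time_per_sample_min = time))
  ord <- order(-out$expected_yield, out$time_per_sample_min,
               out$cost_per_sample,
               out$filter, out$extraction, out$sir)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "catalog") <- catalog
  class(out) <- c("edna_protocol_scores", "data.frame")
  out
}

#' Default decision rules
#'
#' An ordered rule table encoding field guidance for choosing a protocol
#' under study constraints. Each rule has a `name`, a `when` condition over
#' the constraint list, and a `strategy`. Built-in strategies:
#' `"max_yield"` (highest expected yield among feasible protocols),
#' `"min_cost"`, `"min_time"`, and `"balanced"` (fastest filter, then best
#' yield-per-minute among feasible). The default table recommends the
#' highest-yield protocol when yield is the only objective, the cheapest
#' sensitive protocol under severe cost limits, and otherwise the balanced
#' choice (glass fiber + magnetic beads + SIR under the default catalog).
#'
#' Rules can also be loaded from a YAML file ([read_decision_rules()]) so a
#' lab can encode its own decision tree.
#'
#' @return list of rules (class `edna_decision_rules`).
#' @export
default_decision_rules <- function() {
  rules <- list(
    list(name = "maximize_yield_unconstrained",
         when = "objective == 'max_yield' && is.null(max_cost) && is.null(max_time)",
         strategy = "max_yield"),
    list(name = "severe_cost_constraint",
         when = "!is.null(max_cost) && max_cost < 2",
         strategy = "min_cost"),
    list(name = "high_throughput",
         when = "objective == 'min_time'",
         strategy = "min_time"),
    list(name = "balanced_default",
         when = "TRUE",
         strategy = "balanced")
  )
  structure(rules, class = "edna_decision_rules")
}

#' Read decision rules from a YAML file
#' @param path YAML file: a list of rules with `name`, `when`, `strategy`.
#' @export
read_decision_rules <- function(path) {
  rules <- yaml::read_yaml(path)
  structure(rules, class = "edna_decision_rules")
}

apply_strategy <- function(strategy, feasible, catalog = NULL) {
  switch(strategy,
    max_yield = feasible[order(-feasible$expected_yield,
                               feasible$time_per_sample_min,
                               feasible$cost_per_sample), ][1, ],
    min_cost = feasible[order(feasible$cost_per_sample,
                              -feasible$expected_yield), ][1, ],
    min_time = feasible[order(feasible$time_per_sample_min,
                              -feasible$expected_yield), ][1, ],
    balanced = {
      # encode the published decision-tree reasoning: take the fastest
      # filter (turbid water clogs slow membranes), drop extractions that
      # either carry heavy inhibitor loads or sit in the subpar half of the
      # yield range, keep the inhibitor-removal step when compatible, and
      # among what remains choose the fastest protocol
      pick <- feasible
      if (!is.null(catalog)) {
        fr <- catalog[catalog$kind == "filtration", ]
        fast_filter <- fr$method[which.min(fr$batch_time_min / fr$batch_size)]
        er <- catalog[catalog$kind == "extraction", ]
        good_e <- er$method[er$inhibitor <= 0.05 &
                              er$mean_yield >= stats::median(er$mean_yield)]
        if (!length(good_e)) good_e <- er$method
        cand <- pick[pick$filter == fast_filter &
                       pick$extraction %in% good_e & pick$sir, ]
        if (!nrow(cand)) cand <- pick[pick$filter == fast_filter &
                                        pick$extraction %in% good_e, ]
        if (nrow(cand)) pick <- cand
      }
      pick[order(pick$time_per_sample_min, -pick$expected_yield,
                 pick$cost_per_sample), ][1, ]
    },
    stop_config("unknown strategy '%s'", strategy))
}

#' Recommend a protocol under study constraints
#'
#' Filters the scored protocols by the constraints (sensitivity cutoff on
#' detection probability, cost and time caps), then walks the ordered rule
#' table and applies the first rule whose condition holds. When no protocol
#' satisfies the constraints, the nearest-feasible protocol (smallest total
#' constraint violation) is returned with `best_effort = TRUE`.
#'
#' @param scores output of [score_protocols()].
#' @param constraints list with any of `objective`
#'   ("max_yield"/"min_time"/"balanced"), `sensitivity_cutoff` (minimum
#'   detection probability), `max_cost`, `max_time` (minutes/sample).
#' @param rules an `edna_decision_rules` table.
#' @return list of class `edna_recommendation`: `protocol` (one-row
#'   data.frame), `rule` (name of the rule that fired), `trace` (character
#'   log of rule evaluation), `best_effort` flag.
#' @export
recommend_protocol <- function(scores, constraints = list(),
                               rules = default_decision_rules(),
                               catalog = attr(scores, "catalog")) {
  stopifnot(is.data.frame(scores))
  cn <- list(objective = constraints$objective %||% "balanced",
             sensitivity_cutoff = constraints$sensitivity_cutoff,
             max_cost = constraints$max_cost,
             max_time = constraints$max_time)

  feasible <- scores
  if (!is.null(cn$sensitivity_cutoff)) {
    feasible <- feasible[feasible$detection_probability >= cn$sensitivity_cutoff, ]
  }
  if (!is.null(cn$max_cost)) {
    feasible <- feasible[feasible$cost_per_sample <= cn$max_cost, ]
  }
  if (!is.null(cn$max_time)) {
    feasible <- feasible[feasible$time_per_sample_min <= cn$max_time, ]
  }
  best_effort <- nrow(feasible) == 0
  if (best_effort) {
    # nearest-feasible: smallest summed relative violation of the caps
    viol <- rep(0, nrow(scores))
    if (!is.null(cn$sensitivity_cutoff)) {
      viol <- viol + pmax(0, cn$sensitivity_cutoff -
                            scores$detection_probability) /
        max(cn$sensitivity_cutoff, 1e-12)
    }
    if (!is.null(cn$max_cost)) {
      viol <- viol + pmax(0, scores$cost_per_sample - cn$max_cost) / cn$max_cost
    }
    if (!is.null(cn$max_time)) {
      viol <- viol + pmax(0, scores$time_per_sample_min - cn$max_time) /
        cn$max_time
    }
    feasible <- scores[order(viol, -scores$expected_yield), ][1, , drop = FALSE]
  }

  trace <- character(0)
  chosen_rule <- NA_character_
  pick <- NULL
  env <- list2env(cn, parent = baseenv())
  for (r in rules) {
    fire <- isTRUE(eval(parse(text = r$when), envir = env))
    trace <- c(trace, sprintf("rule '%s': %s", r$name,
                              if (fire) "fired" else "skipped"))
    if (fire) {
      chosen_rule <- r$name
      pick <- apply_strategy(r$strategy, feasible, catalog)
      break
    }
  }
  if (is.null(pick)) pick <- apply_strategy("balanced", feasible, catalog)
  structure(list(protocol = pick, rule = chosen_rule, trace = trace,
                 best_effort = best_effort, constraints = cn),
            class = "edna_recommendation")
}

#' @export
print.edna_recommendation <- function(x, ...) {
  p <- x$protocol
  cat(sprintf("Recommended protocol: %s + %s%s\n", p$filter, p$extraction,
              if (p$sir) " + SIR" else ""))
  cat(sprintf("  expected yield %.3g, detection p %.3f, cost %.2f, %.2f min/sample\n",
              p$expected_yield, p$detection_probability, p$cost_per_sample,
              p$time_per_sample_min))
  cat(sprintf("  rule fired: %s%s\n", x$rule,
              if (x$best_effort) " (best effort: constraints infeasible)" else ""))
  invisible(x)
}
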