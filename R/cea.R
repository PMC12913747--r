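# Cost-effectiveness analytics: ICER with dominance classification,
# probabilistic sensitivity analysis, acceptability curves, ICER-plane
# quadrants and one-way sensitivity analysis.

#' Bundle a strategy's cost and QALY totals
#'
#' @param label Strategy label.
#' @param cost Total (discounted) cost, USD.
#' @param qalys Total (discounted) QALYs.
#' @return Object of class `strategy_outcome`.
#' @export
strategy_outcome <- function(label, cost, qalys) {
  stopifnot(is.finite(cost), is.finite(qalys), cost >= 0, qalys >= 0)
  structure(list(label = label, cost = cost, qalys = qalys),
            class = "strategy_outcome")
}

as_outcome <- function(x, label = NULL) {
  if (inherits(x, "strategy_outcome")) return(x)
  if (inherits(x, "cohort_result")) {
    return(strategy_outcome(x$arm, x$cost, x$qalys))
  }
  if (inherits(x, "microsim_result")) {
    return(strategy_outcome(x$arm, x$mean_cost, x$mean_qalys))
  }
  stop("cannot interpret object of class ", class(x)[1], " as a strategy outcome")
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Deltas are comparator minus reference. Classification by sign
#' pattern: more costly and more effective gives an ICER (plane quadrant
#' I); cheaper and more effective is dominant (quadrant IV); more costly
#' and less effective is dominated (quadrant II); cheaper and less
#' effective is cost-saving-but-less-effective, where the ICER is the
#' saving per QALY forgone. A zero effect difference leaves the ICER
#' undefined (flagged, not an error).
#'
#' When the comparator's published headline ICER is supplied via
#' `reported_icer`, the result records the relative discrepancy between
#' it and the ratio recomputed from the totals, and the print method
#' surfaces both.
#'
#' @param reference,comparator `strategy_outcome`s (or `cohort_result` /
#'   `microsim_result` objects).
#' @param reported_icer Optional externally reported ICER to reconcile
#'   against.
#' @return Object of class `cea_result` with `delta_cost`,
#'   `delta_effect`, `icer`, `classification`, and (if supplied)
#'   `reported_icer` and `reported_discrepancy`.
#' @export
compute_icer <- function(reference, comparator, reported_icer = NULL) {
  ref <- as_outcome(reference); cmp <- as_outcome(comparator)
  dC <- cmp$cost - ref$cost
  dE <- cmp$qalys - ref$qalys
  if (dE == 0) {
    classification <- if (dC == 0) "identical" else "undefined"
    icer <- NA_real_
  } else if (dE > 0) {
    if (dC > 0) { classification <- "ICER"; icer <- dC / dE }
    else { classification <- "dominant"; icer <- NA_real_ }
  } else {
    if (dC > 0) { classification <- "dominated"; icer <- NA_real_ }
    else { classification <- "cost-saving-less-effective"; icer <- dC / dE }
  }
  res <- list(reference = ref$label, comparator = cmp$label,
              delta_cost = dC, delta_effect = dE, icer = icer,
              classification = classification)
  if (!is.null(reported_icer)) {
    res$reported_icer <- reported_icer
    res$reported_discrepancy <- if (is.na(icer)) NA_real_ else
      abs(icer - reported_icer) / abs(reported_icer)
  }
  structure(res, class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s vs %s\n", x$comparator, x$reference))
  cat(sprintf("  delta cost:   $%.2f\n", x$delta_cost))
  cat(sprintf("  delta QALYs:  %.4f\n", x$delta_effect))
  cat(sprintf("  class:        %s\n", x$classification))
  if (!is.na(x$icer)) cat(sprintf("  ICER:         $%.2f per QALY\n", x$icer))
  if (!is.null(x$reported_icer)) {
    cat(sprintf("  reported ICER: $%.2f per QALY", x$reported_icer))
    if (!is.na(x$reported_discrepancy) && x$reported_discrepancy > 0.01) {
      cat(sprintf(
        " — differs from the recomputed ratio by %.1f%%; the reported\n",
        100 * x$reported_discrepancy))
      cat("  figure cannot be reproduced from the reported totals alone\n")
    } else cat("\n")
  }
  invisible(x)
}

#' Second-order probabilistic sensitivity analysis
#'
#' For each draw, samples every uncertain parameter from its
#' moment-matched distribution (jointly and independently), renormalizes
#' complementary probability groups, rebuilds the perioperative tree and
#' strategies, evaluates both arms with [run_cohort()], and records the
#' cost/QALY pair per arm plus incrementals. Transition matrices are
#' held fixed (no subject-level counts are published to support a
#' Dirichlet resampling; see `dirichlet_counts` for the option).
#'
#' @param reference,comparator `strategy_model`s; deltas are comparator
#'   minus reference.
#' @param params Base-case `parameter_set`.
#' @param distributions Named list of `distribution_spec`s (default:
#'   [build_distributions()] of `params`).
#' @param config A `model_config` (supplies `n_psa_samples`).
#' @param seed Integer seed.
#' @param n Number of draws (default `config$n_psa_samples`).
#' @param dirichlet_counts Optional list with per-arm origin pseudo-count
#'   vectors enabling Dirichlet resampling of transition-matrix rows;
#'   `NULL` (default) keeps matrices fixed.
#' @return Object of class `psa_samples`: a data frame with one row per
#'   draw (`draw`, `cost_ref`, `qalys_ref`, `cost_cmp`, `qalys_cmp`,
#'   `delta_cost`, `delta_effect`), with the matrix of sampled parameter
#'   values in `attr(, "parameter_draws")` and the number of
#'   complement-group renormalization events in `attr(, "renormalized")`.
#' @export
run_psa <- function(reference, comparator, params,
                    distributions = NULL, config = model_config(),
                    seed = config$rng_seed, n = config$n_psa_samples,
                    dirichlet_counts = NULL) {
  stopifnot(inherits(reference, "strategy_model"),
            inherits(comparator, "strategy_model"))
  if (is.null(distributions)) {
    distributions <- build_distributions(params, warn_shape1 = FALSE)
  }
  set.seed(seed)
  uncertain <- names(distributions)[
    vapply(distributions, function(d) d$family != "fixed", logical(1))]
  # one n x p matrix of parameter draws, sampled up front for speed and
  # clean seeding
  draws <- vapply(distributions, sample_spec, numeric(n), n = n)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n,
                                           dimnames = list(NULL, names(distributions)))
  renorm_events <- 0L
  for (grp in complement_groups()) {
    if (!all(grp %in% colnames(draws))) next
    if (!any(grp %in% uncertain)) next
    s <- rowSums(draws[, grp, drop = FALSE])
    renorm_events <- renorm_events + sum(abs(s - 1) > 1e-12)
    draws[, grp] <- draws[, grp, drop = FALSE] / s
  }

  resample_tm <- function(strategy, counts) {
    if (is.null(counts)) return(strategy)
    for (slot in c("cycle1_matrix", "steady_matrix")) {
      m <- tm_matrix(strategy[[slot]])
      for (i in which(rowSums(m) > 0 & counts > 0)) {
        alpha <- m[i, ] * counts[i]
        g <- stats::rgamma(N_STATES, shape = ifelse(alpha > 0, alpha, 0))
        if (sum(g) > 0) m[i, ] <- g / sum(g)
      }
      strategy[[slot]] <- transition_matrix(m, normalize = FALSE)
    }
    strategy
  }

  out <- matrix(NA_real_, n, 4)
  base <- params
  for (k in seq_len(n)) {
    pk <- set_param(base, draws[k, ], renormalize = FALSE)
    ref_k <- if (!is.null(dirichlet_counts)) {
      resample_tm(reference, dirichlet_counts$reference)
    } else reference
    cmp_k <- if (!is.null(dirichlet_counts)) {
      resample_tm(comparator, dirichlet_counts$comparator)
    } else comparator
    r <- run_cohort(ref_k, config, pk)
    s <- run_cohort(cmp_k, config, pk)
    out[k, ] <- c(r$cost, r$qalys, s$cost, s$qalys)
  }
  samples <- data.frame(draw = seq_len(n),
                        cost_ref = out[, 1], qalys_ref = out[, 2],
                        cost_cmp = out[, 3], qalys_cmp = out[, 4])
  samples$delta_cost <- samples$cost_cmp - samples$cost_ref
  samples$delta_effect <- samples$qalys_cmp - samples$qalys_ref
  attr(samples, "parameter_draws") <- draws
  attr(samples, "renormalized") <- renorm_events
  attr(samples, "seed") <- seed
  class(samples) <- c("psa_samples", "data.frame")
  samples
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value `lambda`, the probability that the
#' comparator is cost-effective is the fraction of PSA draws with
#' positive net monetary benefit `lambda * delta_effect - delta_cost`.
#' Ties (NMB exactly 0) count as not cost-effective under the default
#' rule.
#'
#' @param samples A `psa_samples` data frame (needs `delta_cost`,
#'   `delta_effect`).
#' @param wtp_grid Ascending WTP values (USD/QALY).
#' @param tie_rule `"not_effective"` (default) or `"effective"`.
#' @return Object of class `ceac_curve`: data frame with columns `wtp`
#'   and `probability`.
#' @export
ceac <- function(samples, wtp_grid = model_config()$wtp_grid,
                 tie_rule = c("not_effective", "effective")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(nrow(samples) >= 1)
  if (is.unsorted(wtp_grid, strictly = TRUE)) {
    stop("wtp_grid must be strictly ascending")
  }
  prob <- vapply(wtp_grid, function(l) {
    nmb <- l * samples$delta_effect - samples$delta_cost
    if (tie_rule == "not_effective") mean(nmb > 0) else mean(nmb >= 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

#' ICER-plane quadrant summary of PSA draws
#'
#' Quadrants of the cost-effectiveness plane by sign of (delta effect,
#' delta cost), labelled as in the source field's convention:
#' I = more effective & more costly, II = less effective & more costly
#' (dominated), III = less effective & cheaper, IV = more effective &
#' cheaper (dominant). Also reports the fraction of quadrant-I draws
#' lying below the WTP ray (ICER below `wtp`).
#'
#' @param samples A `psa_samples` data frame.
#' @param wtp WTP threshold (USD/QALY) for the quadrant-I sub-fraction.
#' @return Object of class `quadrant_summary` (a list).
#' @export
quadrant_summary <- function(samples, wtp = 50000) {
  stopifnot(nrow(samples) >= 1)
  dE <- samples$delta_effect; dC <- samples$delta_cost
  q1 <- dE > 0 & dC > 0
  q2 <- dE <= 0 & dC > 0
  q3 <- dE <= 0 & dC <= 0
  q4 <- dE > 0 & dC <= 0
  n <- length(dE)
  below <- q1 & (dC < wtp * dE)
  structure(list(
    fractions = c(I = mean(q1), II = mean(q2), III = mean(q3), IV = mean(q4)),
    quadrant_I_below_ray = sum(below) / n,
    wtp = wtp, n = n), class = "quadrant_summary")
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat(sprintf("<quadrant_summary> %d draws, WTP ray $%g/QALY\n", x$n, x$wtp))
  f <- x$fractions
  cat(sprintf("  I  (more effective, more costly): %.4f\n", f["I"]))
  cat(sprintf("  II (dominated):                   %.4f\n", f["II"]))
  cat(sprintf("  III(less effective, cheaper):     %.4f\n", f["III"]))
  cat(sprintf("  IV (dominant):                    %.4f\n", f["IV"]))
  cat(sprintf("  I below WTP ray:                  %.4f\n",
              x$quadrant_I_below_ray))
  invisible(x)
}

#' One-way sensitivity analysis over a single parameter
#'
#' Re-evaluates the base-case model at each grid value of one parameter
#' (all else fixed) and reports the resulting incremental comparison.
#'
#' @param param_name Parameter to vary.
#' @param low,high Range endpoints, `low < high` (equal endpoints give a
#'   degenerate constant analysis only when `low == high` is explicit
#'   via a length-one `values`).
#' @param steps Number of grid points (>= 2).
#' @param reference,comparator `strategy_model`s.
#' @param params Base-case `parameter_set`.
#' @param config A `model_config`.
#' @param values Optional explicit value grid overriding
#'   `low`/`high`/`steps`.
#' @return Data frame with one row per grid value: `value`,
#'   `delta_cost`, `delta_effect`, `icer`, `classification`.
#' @export
one_way_sa <- function(param_name, low, high, steps = 11,
                       reference, comparator, params,
                       config = model_config(), values = NULL) {
  if (is.null(values)) {
    stopifnot(low < high, steps >= 2)
    values <- seq(low, high, length.out = steps)
  }
  param_value(params, param_name)  # errors on unknown parameter
  rows <- lapply(values, function(v) {
    pk <- set_param(params, stats::setNames(v, param_name),
                    renormalize = FALSE)
    r <- run_cohort(reference, config, pk)
    s <- run_cohort(comparator, config, pk)
    res <- compute_icer(r, s)
    data.frame(value = v, delta_cost = res$delta_cost,
               delta_effect = res$delta_effect, icer = res$icer,
               classification = res$classification)
  })
  do.call(rbind, rows)
}
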