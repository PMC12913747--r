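# Global run configuration.

#' Model run configuration
#'
#' @param horizon_years Number of annual Markov cycles (default 33).
#' @param cycle_length_years Cycle length; the model is annual, so this
#'   is fixed at 1.
#' @param discount_rate_costs Annual discount rate applied to costs
#'   (fraction per year). Default 0: the bundled reference scenario
#'   accrues undiscounted totals, matching the convention its published
#'   headline figures were computed under; set 0.03 for the usual US
#'   panel recommendation.
#' @param discount_rate_qalys Annual discount rate applied to QALYs.
#'   Default 0 (same rationale).
#' @param n_psa_samples Number of probabilistic-sensitivity-analysis
#'   draws (default 10000).
#' @param n_microsim_individuals Default number of simulated individuals
#'   for microsimulation runs.
#' @param wtp_grid Ascending willingness-to-pay grid (USD/QALY) for
#'   acceptability curves. Default $0-$100,000 in $1,000 steps (contains
#'   the $10,000 and $50,000 benchmarks).
#' @param rng_seed Integer seed used by seeded operations when the caller
#'   does not pass one explicitly.
#' @return Object of class `model_config` (a list).
#' @export
model_config <- function(horizon_years = 33L,
                         cycle_length_years = 1,
                         discount_rate_costs = 0,
                         discount_rate_qalys = 0,
                         n_psa_samples = 10000L,
                         n_microsim_individuals = 10000L,
                         wtp_grid = seq(0, 100000, by = 1000),
                         rng_seed = 20251004L) {
  horizon_years <- as.integer(horizon_years)
  stopifnot(horizon_years >= 1,
            cycle_length_years == 1,
            discount_rate_costs >= 0,
            discount_rate_qalys >= 0,
            n_psa_samples >= 1,
            n_microsim_individuals >= 1,
            length(wtp_grid) >= 1)
  if (is.unsorted(wtp_grid, strictly = TRUE)) {
    stop("wtp_grid must be strictly ascending")
  }
  cfg <- list(horizon_years = horizon_years,
              cycle_length_years = cycle_length_years,
              discount_rate_costs = discount_rate_costs,
              discount_rate_qalys = discount_rate_qalys,
              n_psa_samples = as.integer(n_psa_samples),
              n_microsim_individuals = as.integer(n_microsim_individuals),
              wtp_grid = as.numeric(wtp_grid),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "model_config"
  cfg
}

#' Read a run configuration from JSON or YAML
#'
#' Keys must match the [model_config()] argument names; absent keys take
#' the defaults.
#'
#' @param path `.json` or `.yaml`/`.yml` file.
#' @return A `model_config`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML config requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  unknown <- setdiff(names(vals), names(formals(model_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(model_config, vals)
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  horizon: %d annual cycles\n", x$horizon_years))
  cat(sprintf("  discounting: costs %.1f%%/yr, QALYs %.1f%%/yr\n",
              100 * x$discount_rate_costs, 100 * x$discount_rate_qalys))
  cat(sprintf("  PSA draws: %d; microsim individuals: %d\n",
              x$n_psa_samples, x$n_microsim_individuals))
  cat(sprintf("  WTP grid: %d points in [%g, %g]\n",
              length(x$wtp_grid), min(x$wtp_grid), max(x$wtp_grid)))
  invisible(x)
}
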