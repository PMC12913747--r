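# EQ-5D scoring, utility binning, and the ten utility-decile health
# states of the Markov model.

EQ5D_DOMAINS <- c("mo", "sc", "ua", "pd", "ad")

#' Construct an additive EQ-5D value set
#'
#' An additive tariff: utility = 1 - intercept - sum of per-domain,
#' per-level decrements, clamped below at `floor`. Level 1 of every
#' domain must carry decrement 0 and, with `intercept = 0`, the
#' full-health response scores exactly 1.
#'
#' @param decrements Data frame with columns `domain` (one of
#'   `mo, sc, ua, pd, ad`), `level` (integer >= 1) and `decrement`
#'   (nonnegative). Every domain must cover levels `1..n_levels`.
#' @param intercept Constant subtracted from every non-full-health score
#'   (0 in the bundled synthetic tariff).
#' @param floor Lowest attainable utility (may be negative).
#' @param n_levels Levels per domain (3 for EQ-5D-3L, 5 for -5L).
#' @return Object of class `value_set`.
#' @export
value_set <- function(decrements, intercept = 0, floor = -0.11, n_levels = 3L) {
  stopifnot(is.data.frame(decrements),
            all(c("domain", "level", "decrement") %in% names(decrements)),
            floor <= 1, n_levels >= 2)
  decrements$domain <- as.character(decrements$domain)
  decrements$level <- as.integer(decrements$level)
  decrements$decrement <- as.numeric(decrements$decrement)
  if (!setequal(unique(decrements$domain), EQ5D_DOMAINS)) {
    stop("value set must cover exactly the domains: ",
         paste(EQ5D_DOMAINS, collapse = ", "))
  }
  if (any(decrements$decrement < 0)) stop("decrements must be nonnegative")
  for (d in EQ5D_DOMAINS) {
    lv <- sort(decrements$level[decrements$domain == d])
    if (!identical(lv, seq_len(n_levels))) {
      stop("domain ", d, " must define levels 1..", n_levels, " exactly once")
    }
    if (decrements$decrement[decrements$domain == d & decrements$level == 1] != 0) {
      stop("level-1 decrement must be 0 (domain ", d, ")")
    }
  }
  # lookup matrix: rows = domains, cols = levels
  lut <- matrix(0, nrow = length(EQ5D_DOMAINS), ncol = n_levels,
                dimnames = list(EQ5D_DOMAINS, NULL))
  for (i in seq_len(nrow(decrements))) {
    lut[decrements$domain[i], decrements$level[i]] <- decrements$decrement[i]
  }
  vs <- list(decrements = decrements, lut = lut, intercept = intercept,
             floor = floor, n_levels = as.integer(n_levels))
  class(vs) <- "value_set"
  vs
}

#' Bundled synthetic EQ-5D-3L value set
#'
#' A stand-in additive tariff (clearly synthetic, not any national value
#' set): full-health anchor 1.0, floor -0.11, plausible decrement
#' ordering (pain and self-care weigh most). Supply a published tariff
#' via [read_value_set()] for real analyses.
#'
#' @return A `value_set`.
#' @export
default_value_set <- function() {
  dec <- data.frame(
    domain = rep(EQ5D_DOMAINS, each = 3),
    level = rep(1:3, times = 5),
    decrement = c(
      0, 0.07, 0.31,   # mobility
      0, 0.10, 0.34,   # self-care
      0, 0.04, 0.21,   # usual activities
      0, 0.12, 0.39,   # pain/discomfort
      0, 0.09, 0.26)   # anxiety/depression
  )
  value_set(dec, intercept = 0, floor = -0.11, n_levels = 3L)
}

#' Read a value set from CSV
#'
#' Layout: rows `domain,level,decrement` plus metadata rows with
#' `domain` equal to `intercept` or `floor` (their value in the
#' `decrement` column).
#'
#' @param path CSV path.
#' @param n_levels Levels per domain.
#' @return A `value_set`.
#' @export
read_value_set <- function(path, n_levels = 3L) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  meta <- df$domain %in% c("intercept", "floor")
  getmeta <- function(key, default) {
    v <- df$decrement[df$domain == key]
    if (length(v)) as.numeric(v[1]) else default
  }
  value_set(df[!meta, ], intercept = getmeta("intercept", 0),
            floor = getmeta("floor", -0.11), n_levels = n_levels)
}

#' Write a value set to CSV
#'
#' @param vs A `value_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_value_set <- function(vs, path) {
  stopifnot(inherits(vs, "value_set"))
  df <- rbind(vs$decrements[, c("domain", "level", "decrement")],
              data.frame(domain = c("intercept", "floor"), level = NA,
                         decrement = c(vs$intercept, vs$floor)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Score EQ-5D responses to health-utility values
#'
#' @param response Data frame (or single named vector/list) with integer
#'   columns `mo, sc, ua, pd, ad` — the five domain levels (mobility,
#'   self-care, usual activities, pain/discomfort, anxiety/depression).
#' @param valueset A `value_set` (default [default_value_set()]).
#' @return Numeric vector of utilities, one per response row:
#'   `1 - intercept - sum(decrements)`, clamped below at the tariff
#'   floor.
#' @export
score_eq5d <- function(response, valueset = default_value_set()) {
  stopifnot(inherits(valueset, "value_set"))
  if (!is.data.frame(response)) response <- as.data.frame(as.list(response))
  missing_dom <- setdiff(EQ5D_DOMAINS, names(response))
  if (length(missing_dom)) {
    stop("response lacks domain(s): ", paste(missing_dom, collapse = ", "))
  }
  lv <- as.matrix(response[, EQ5D_DOMAINS])
  storage.mode(lv) <- "integer"
  if (anyNA(lv) || any(lv < 1L) || any(lv > valueset$n_levels)) {
    stop("domain levels must be integers in 1..", valueset$n_levels)
  }
  dec <- vapply(seq_along(EQ5D_DOMAINS), function(j) {
    valueset$lut[j, lv[, j]]
  }, numeric(nrow(lv)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  huv <- 1 - valueset$intercept - rowSums(dec)
  pmax(huv, valueset$floor)
}

#' Bin a health-utility value into one of the ten Markov states
#'
#' States are utility deciles: state 1 covers `[0, 0.1)` (reported as
#' 0-0.099) up to state 10 covering `[0.9, 1]` (closed top). Negative
#' utilities (possible under tariffs with a negative floor) clamp into
#' state 1 with a warning.
#'
#' @param huv Numeric vector of utilities, each at most 1.
#' @return Integer vector of state indices in 1..10.
#' @export
bin_huv <- function(huv) {
  huv <- as.numeric(huv)
  if (anyNA(huv)) stop("huv contains NA")
  if (any(huv > 1)) stop("utility above 1: ", max(huv))
  if (any(huv < 0)) {
    warning(sum(huv < 0), " negative utility value(s) clamped into state 1")
    huv[huv < 0] <- 0
  }
  pmin(as.integer(floor(huv * 10)) + 1L, N_STATES)
}

#' Display labels of the ten utility-bin states
#'
#' @return Character vector (`"0-0.099"` ... `"0.9-1"`).
#' @export
state_bin_labels <- function() {
  c("0-0.099", "0.1-0.199", "0.2-0.299", "0.3-0.399", "0.4-0.499",
    "0.5-0.599", "0.6-0.699", "0.7-0.799", "0.8-0.899", "0.9-1")
}

#' Representative utility of each state
#'
#' Defaults to the bin midpoints 0.05, 0.15, ..., 0.95 (the within-bin
#' placement is unidentified once utilities are binned).
#'
#' @return Numeric vector of length 10.
#' @export
state_utilities <- function() {
  seq(0.05, 0.95, by = 0.1)
}

#' Annual cost of each living state
#'
#' Maps the ten annual Markov state costs (`cMarkov1..cMarkov10`) onto
#' the states. Default orientation `"healthiest_cheapest"` attaches
#' `cMarkov1` (the lowest cost) to state 10 (utility 0.9-1) and
#' `cMarkov10` to state 1 — sicker patients incur more cost.
#' `"sickest_cheapest"` reverses this.
#'
#' @param params A `parameter_set`.
#' @param orientation `"healthiest_cheapest"` (default) or
#'   `"sickest_cheapest"`.
#' @return Numeric vector of length 10, cost of states 1..10.
#' @export
state_costs <- function(params, orientation = c("healthiest_cheapest",
                                                "sickest_cheapest")) {
  orientation <- match.arg(orientation)
  costs <- unname(param_value(params, paste0("cMarkov", 1:10)))
  if (orientation == "healthiest_cheapest") rev(costs) else costs
}
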