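# Model parameter table: named probabilities and costs with uncertainty.

#' Names of the parameters every complete model table must provide
#'
#' Thirteen perioperative/revision probabilities and nineteen costs
#' (including the ten annual Markov state costs).
#'
#' @return Named list with components `probability` and `cost`, each a
#'   character vector of required parameter names.
#' @export
required_parameters <- function() {
  list(
    probability = c(
      "pDeath", "pIntraOpComp", "pNoIntraOpComp", "pNoPostOpComp",
      "pPostOpComp", "pPostOpInfection", "pPostOpEpistaxis",
      "pPostOpCSFleak", "pPostOpEpistaxisCons", "pPostOpEpistaxisOR",
      "pPostOpCSFleakCons", "pPostOpCSFleakOR", "pRevisionESS"
    ),
    cost = c(
      "cDeath", "cESS", "cMedical", "cESSMajorComp", "cInfection",
      "cBleedCons", "cBleedOR", "cCSFCons", "cCSFOR",
      paste0("cMarkov", 1:10)
    )
  )
}

# Complementary branch groups that must sum to one. Order matters only
# for reporting.
complement_groups <- function() {
  list(
    intraop    = c("pIntraOpComp", "pNoIntraOpComp"),
    postop     = c("pPostOpComp", "pNoPostOpComp"),
    postop_type = c("pPostOpInfection", "pPostOpEpistaxis", "pPostOpCSFleak"),
    epistaxis  = c("pPostOpEpistaxisCons", "pPostOpEpistaxisOR"),
    csf_leak   = c("pPostOpCSFleakCons", "pPostOpCSFleakOR")
  )
}

#' Construct a validated parameter set
#'
#' @param df Data frame with columns `name`, `mean`, `se` and optionally
#'   `description` and `source`. Parameter kind is inferred from the name
#'   prefix (`p` = probability, `c` = cost).
#' @param renormalize Renormalize complementary probability groups whose
#'   sum deviates from 1 by at most `tol` (deviations beyond `tol` are
#'   errors). Default `TRUE`.
#' @param tol Tolerance for complementary-group renormalization.
#' @param require_complete Require every name from
#'   [required_parameters()]. Extra names are always preserved.
#' @return Object of class `parameter_set` (a data frame).
#' @export
parameter_set <- function(df, renormalize = TRUE, tol = 0.002,
                          require_complete = TRUE) {
  stopifnot(is.data.frame(df))
  need <- c("name", "mean", "se")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("parameter table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$name <- as.character(df$name)
  df$mean <- as.numeric(df$mean)
  df$se <- as.numeric(df$se)
  df$se[is.na(df$se)] <- 0
  if (is.null(df$description)) df$description <- ""
  if (is.null(df$source)) df$source <- ""
  if (anyDuplicated(df$name)) {
    stop("duplicated parameter name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  df$kind <- ifelse(startsWith(df$name, "p"), "probability", "cost")

  if (require_complete) {
    req <- unlist(required_parameters(), use.names = FALSE)
    absent <- setdiff(req, df$name)
    if (length(absent)) {
      stop("missing required parameter(s): ", paste(absent, collapse = ", "))
    }
  }
  if (any(is.na(df$mean))) {
    stop("non-numeric mean for parameter(s): ",
         paste(df$name[is.na(df$mean)], collapse = ", "))
  }
  bad_se <- df$se < 0
  if (any(bad_se)) {
    stop("negative se for parameter(s): ", paste(df$name[bad_se], collapse = ", "))
  }
  is_p <- df$kind == "probability"
  bad_p <- is_p & (df$mean < 0 | df$mean > 1)
  if (any(bad_p)) {
    stop("probability outside [0, 1] for parameter(s): ",
         paste(sprintf("%s (mean = %g)", df$name[bad_p], df$mean[bad_p]),
               collapse = ", "))
  }
  bad_c <- !is_p & df$mean < 0
  if (any(bad_c)) {
    stop("negative cost for parameter(s): ",
         paste(df$name[bad_c], collapse = ", "))
  }

  out <- df[, c("name", "description", "mean", "se", "source", "kind")]
  class(out) <- c("parameter_set", "data.frame")
  if (renormalize) out <- renormalize_complements(out, tol = tol)
  out
}

# Proportionally rescale each fully-present complementary group so it sums
# to exactly 1; deviation beyond tol is an error (likely a transcription
# problem, not rounding).
renormalize_complements <- function(params, tol = 0.002) {
  for (grp in complement_groups()) {
    if (!all(grp %in% params$name)) next
    idx <- match(grp, params$name)
    s <- sum(params$mean[idx])
    dev <- abs(s - 1)
    if (dev > tol) {
      stop(sprintf(
        "complementary group {%s} sums to %.4f (deviation %.4f > tol %g)",
        paste(grp, collapse = ", "), s, dev, tol))
    }
    if (dev > 0) params$mean[idx] <- params$mean[idx] / s
  }
  params
}

#' Load a parameter table from CSV or JSON
#'
#' The CSV layout is `name,description,mean,se,source`; a blank or absent
#' `se` marks a fixed parameter. A JSON array of objects with the same
#' fields is accepted. Complementary probability groups (e.g.
#' intraoperative complication vs none) are proportionally renormalized
#' to sum to 1 when within `tol`.
#'
#' @param path File path (`.csv` or `.json`).
#' @inheritParams parameter_set
#' @return A [parameter_set()].
#' @export
load_parameters <- function(path, renormalize = TRUE, tol = 0.002,
                            require_complete = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  }
  parameter_set(df, renormalize = renormalize, tol = tol,
                require_complete = require_complete)
}

#' Write a parameter table to CSV
#'
#' Inverse of [load_parameters()]; `load_parameters(write_parameters(p))`
#' reproduces `p`.
#'
#' @param params A `parameter_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  utils::write.csv(
    params[, c("name", "description", "mean", "se", "source")],
    path, row.names = FALSE)
  invisible(path)
}

#' Look up parameter means by name
#'
#' @param params A `parameter_set`.
#' @param names Character vector of parameter names.
#' @return Named numeric vector of means.
#' @export
param_value <- function(params, names) {
  idx <- match(names, params$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ", paste(names[is.na(idx)], collapse = ", "))
  }
  stats::setNames(params$mean[idx], names)
}

#' Replace parameter means
#'
#' @param params A `parameter_set`.
#' @param values Named numeric vector of new means.
#' @param renormalize Re-apply complementary-group renormalization.
#' @return Modified `parameter_set`.
#' @export
set_param <- function(params, values, renormalize = FALSE) {
  idx <- match(names(values), params$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ",
         paste(names(values)[is.na(idx)], collapse = ", "))
  }
  params$mean[idx] <- as.numeric(values)
  out <- parameter_set(as.data.frame(params), renormalize = renormalize,
                       require_complete = FALSE)
  out
}

#' Check complementary probability groups
#'
#' Reports, for each declared complementary pair or triple (e.g.
#' postoperative complication vs none), the deviation of the summed means
#' from 1 and whether it exceeds `tol`.
#'
#' @param params A `parameter_set`.
#' @param tol Nonnegative flag threshold.
#' @return Data frame with columns `group`, `members`, `sum`,
#'   `deviation`, `flagged`.
#' @export
validate_complement_pairs <- function(params, tol = 0.002) {
  stopifnot(tol >= 0)
  grps <- complement_groups()
  res <- lapply(names(grps), function(g) {
    members <- grps[[g]]
    present <- members %in% params$name
    if (!all(present)) {
      return(data.frame(group = g, members = paste(members, collapse = "+"),
                        sum = NA_real_, deviation = NA_real_, flagged = NA))
    }
    s <- sum(param_value(params, members))
    data.frame(group = g, members = paste(members, collapse = "+"),
               sum = s, deviation = abs(s - 1), flagged = abs(s - 1) > tol)
  })
  do.call(rbind, res)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d parameters (%d probabilities, %d costs)\n",
              nrow(x), sum(x$kind == "probability"), sum(x$kind == "cost")))
  print.data.frame(x[, c("name", "mean", "se", "kind")], row.names = FALSE, ...)
  invisible(x)
}
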