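# Transition matrices over the ten utility-bin states: construction,
# row normalization, CSV I/O, and estimation from longitudinal panels.

#' Construct a transition matrix over the ten utility-bin states
#'
#' @param mat 10x10 numeric matrix, rows = origin state, columns =
#'   destination state (state 1 = utility 0-0.099 ... state 10 = 0.9-1).
#'   Each row must be all zero (an unobserved origin) or sum to 1 within
#'   `tol`.
#' @param arm Arm label (e.g. `"medical"`, `"surgical"`).
#' @param phase Phase label (e.g. `"cycle1"`, `"steady"`).
#' @param counts Optional 10-vector of origin-state subject counts
#'   retained from estimation.
#' @param normalize Divide each nonzero row by its sum (default TRUE).
#' @param tol Allowed deviation of a nonzero row sum from 1 before
#'   normalization.
#' @return Object of class `transition_matrix`.
#' @export
transition_matrix <- function(mat, arm = NA_character_, phase = NA_character_,
                              counts = NULL, normalize = TRUE, tol = 0.02) {
  mat <- as.matrix(mat)
  if (!all(dim(mat) == c(N_STATES, N_STATES))) {
    stop("transition matrix must be 10x10, got ",
         paste(dim(mat), collapse = "x"))
  }
  if (any(mat < 0)) stop("transition probabilities must be nonnegative")
  dimnames(mat) <- list(state_bin_labels(), state_bin_labels())
  rs <- rowSums(mat)
  nonzero <- rs > 0
  bad <- nonzero & abs(rs - 1) > tol
  if (any(bad)) {
    stop(sprintf("row(s) %s sum to %s (outside 1 +/- %g)",
                 paste(state_bin_labels()[bad], collapse = ", "),
                 paste(sprintf("%.4f", rs[bad]), collapse = ", "), tol))
  }
  if (normalize && any(nonzero)) {
    mat[nonzero, ] <- mat[nonzero, , drop = FALSE] / rs[nonzero]
  }
  structure(list(mat = mat, arm = arm, phase = phase, counts = counts),
            class = "transition_matrix")
}

#' Renormalize the rows of a transition matrix
#'
#' Divides each nonzero row by its sum; all-zero (unobserved-origin) rows
#' are untouched. Rows whose sum deviates from 1 by more than `tol` raise
#' an error naming the row — printed tables commonly carry rounding drift
#' of about 0.01, but larger deviations signal transcription problems.
#'
#' @param tm A `transition_matrix` (or bare 10x10 matrix).
#' @param tol Allowed pre-normalization deviation from 1.
#' @return A `transition_matrix` with exactly row-stochastic nonzero rows.
#' @export
normalize_rows <- function(tm, tol = 0.02) {
  if (inherits(tm, "transition_matrix")) {
    transition_matrix(tm$mat, arm = tm$arm, phase = tm$phase,
                      counts = tm$counts, normalize = TRUE, tol = tol)
  } else {
    transition_matrix(tm, normalize = TRUE, tol = tol)
  }
}

tm_matrix <- function(tm) {
  if (inherits(tm, "transition_matrix")) tm$mat else as.matrix(tm)
}

#' Replace unobserved-origin rows with self-loops
#'
#' An all-zero row means no subject was observed leaving that state, so
#' the estimated dynamics are silent about it; the Markov engine refuses
#' to evolve a cohort into such a state. This patch adopts the minimal
#' assumption that an occupant of an unobserved state stays put, and
#' flags the matrix as modified.
#'
#' @param tm A `transition_matrix`.
#' @return A `transition_matrix` with identity rows in place of zero
#'   rows and attribute `patched_states` listing the affected states.
#' @export
patch_unobserved_rows <- function(tm) {
  m <- tm_matrix(tm)
  zero <- rowSums(m) == 0
  for (i in which(zero)) m[i, i] <- 1
  out <- transition_matrix(m, arm = tm$arm, phase = tm$phase,
                           counts = tm$counts, normalize = FALSE)
  out$patched_states <- which(zero)
  out
}

#' Read a transition matrix from CSV
#'
#' Expects an 11x11 layout: first row and first column are the bin
#' labels (`0-0.099` ... `0.9-1`; en dashes accepted).
#'
#' @param path CSV path.
#' @param arm,phase Labels attached to the result.
#' @param normalize,tol Passed to [transition_matrix()].
#' @return A `transition_matrix`.
#' @export
read_transition_matrix <- function(path, arm = NA_character_,
                                   phase = NA_character_,
                                   normalize = TRUE, tol = 0.02) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        strip.white = TRUE)
  labels_in <- gsub("–", "-", as.character(df[[1]]))
  if (!identical(labels_in, state_bin_labels())) {
    stop("row labels in ", path, " do not match the ten utility bins")
  }
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "double"
  transition_matrix(m, arm = arm, phase = phase,
                    normalize = normalize, tol = tol)
}

#' Write a transition matrix to CSV
#'
#' @param tm A `transition_matrix`.
#' @param path Output path.
#' @param provenance Optional provenance tag written as a leading
#'   `#`-comment line (e.g. `"reference"` or `"synthetic"`).
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(tm, path, provenance = NULL) {
  m <- tm_matrix(tm)
  df <- data.frame(state = state_bin_labels(), m, check.names = FALSE)
  names(df) <- c("state", state_bin_labels())
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# provenance: ", provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

check_panel <- function(panel) {
  need <- c("subject", "arm", "wave", "huv")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("panel lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(panel$wave < 0) || any(panel$wave != floor(panel$wave))) {
    stop("waves must be nonnegative integers")
  }
  key <- paste(panel$subject, panel$arm, panel$wave)
  if (anyDuplicated(key)) stop("at most one record per subject per wave")
  invisible(panel)
}

#' Estimate a transition matrix from a longitudinal utility panel
#'
#' Entry (i, j) is the fraction of the arm's subjects observed in state
#' i at `wave_from` and state j at `wave_to`, among those in state i at
#' `wave_from` with both waves recorded. Origin states with no subjects
#' yield all-zero rows; origin counts are retained.
#'
#' @param panel Data frame with columns `subject`, `arm`, `wave`, `huv`.
#' @param wave_from,wave_to Wave indices (years from baseline),
#'   `wave_to > wave_from`.
#' @param arm Arm label to subset on.
#' @return A `transition_matrix` with `counts` set.
#' @export
estimate_transitions <- function(panel, wave_from, wave_to, arm) {
  check_panel(panel)
  stopifnot(wave_to > wave_from)
  p <- panel[panel$arm == arm, ]
  a <- p[p$wave == wave_from, c("subject", "huv")]
  b <- p[p$wave == wave_to, c("subject", "huv")]
  m <- merge(a, b, by = "subject", suffixes = c("_from", "_to"))
  if (nrow(m) == 0) {
    stop("no subjects in arm '", arm, "' observed at both wave ",
         wave_from, " and wave ", wave_to)
  }
  from <- bin_huv(m$huv_from)
  to <- bin_huv(m$huv_to)
  counts <- matrix(0, N_STATES, N_STATES)
  for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
  n_origin <- rowSums(counts)
  probs <- counts
  nz <- n_origin > 0
  probs[nz, ] <- probs[nz, , drop = FALSE] / n_origin[nz]
  transition_matrix(probs, arm = arm,
                    phase = paste0("wave", wave_from, "-", wave_to),
                    counts = n_origin, normalize = FALSE)
}

#' Estimate the entrance distribution from baseline observations
#'
#' @param panel Data frame with columns `subject`, `arm`, `wave`, `huv`.
#' @param arm Arm label to subset on.
#' @return Probability vector over the ten states (sums to 1), built as
#'   the normalized histogram of wave-0 binned utilities.
#' @export
estimate_entrance <- function(panel, arm) {
  check_panel(panel)
  p <- panel[panel$arm == arm & panel$wave == 0, ]
  if (nrow(p) == 0) stop("no wave-0 records for arm '", arm, "'")
  tab <- tabulate(bin_huv(p$huv), nbins = N_STATES)
  stats::setNames(tab / sum(tab), state_bin_labels())
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<transition_matrix> arm = %s, phase = %s\n", x$arm, x$phase))
  if (!is.null(x$patched_states) && length(x$patched_states)) {
    cat("  unobserved rows patched with self-loops: state(s) ",
        paste(x$patched_states, collapse = ", "), "\n", sep = "")
  }
  print(round(x$mat, digits), ...)
  invisible(x)
}
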