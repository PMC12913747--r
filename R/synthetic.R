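# Synthetic longitudinal cohorts: generate utility panels from known
# entrance distributions and transition matrices, and EQ-5D responses
# consistent with a panel, so every pipeline stage is testable without
# patient data.

#' Specification for a synthetic two-arm utility panel
#'
#' Defaults mirror the reference scenario's study conditions: 96
#' surgical subjects followed annually for 5 years and 48 medical
#' subjects followed annually for 2 years, with a shared entrance
#' distribution and per-arm transition matrices.
#'
#' @param arms Named list; each element is a list with `n` (subjects),
#'   `entrance` (probability 10-vector), `cycle1` and `steady`
#'   (`transition_matrix`), and `n_waves` (follow-up years).
#' @param jitter Within-bin utility placement rule; `"uniform"` draws
#'   the emitted utility uniformly over the occupied bin (the only rule
#'   implemented — within-bin placement is unidentified once utilities
#'   are binned).
#' @param seed Integer seed.
#' @return Object of class `panel_spec`.
#' @export
panel_spec <- function(arms = NULL, jitter = "uniform", seed = 20251004L) {
  if (is.null(arms)) {
    fx <- crs_fixture()
    arms <- list(
      surgical = list(n = 96L, entrance = fx$entrance,
                      cycle1 = fx$matrices$surgical_cycle1,
                      steady = fx$matrices$surgical_steady, n_waves = 5L),
      medical = list(n = 48L, entrance = fx$entrance,
                     cycle1 = fx$matrices$medical_cycle1,
                     steady = fx$matrices$medical_steady, n_waves = 2L))
  }
  stopifnot(jitter == "uniform", length(arms) >= 1, !is.null(names(arms)))
  for (nm in names(arms)) {
    a <- arms[[nm]]
    stopifnot(a$n >= 1, a$n_waves >= 1,
              length(a$entrance) == N_STATES,
              abs(sum(a$entrance) - 1) < 1e-9)
  }
  structure(list(arms = arms, jitter = jitter, seed = as.integer(seed)),
            class = "panel_spec")
}

# uniform draw within a state's utility bin ([0,0.1) ... [0.9,1])
draw_in_bin <- function(state) {
  lo <- (state - 1) / 10
  lo + stats::runif(length(state)) / 10
}

#' Generate a synthetic longitudinal utility panel
#'
#' Per subject: a wave-0 state drawn from the arm's entrance
#' distribution, evolution through the arm's cycle-1 matrix (wave 0 to
#' 1) and steady matrix (later waves), and an emitted utility uniform
#' within the occupied bin at every wave. Reproducible per seed.
#'
#' @param spec A `panel_spec`.
#' @return Data frame with columns `subject`, `arm`, `wave`, `huv`
#'   (one record per subject per wave).
#' @export
generate_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  rows <- list()
  for (arm in names(spec$arms)) {
    a <- spec$arms[[arm]]
    m1 <- tm_matrix(a$cycle1); ms <- tm_matrix(a$steady)
    state <- sample.int(N_STATES, a$n, replace = TRUE, prob = a$entrance)
    subj <- sprintf("%s_%04d", arm, seq_len(a$n))
    rows[[length(rows) + 1]] <- data.frame(
      subject = subj, arm = arm, wave = 0L, huv = draw_in_bin(state))
    for (w in seq_len(a$n_waves)) {
      m <- if (w == 1) m1 else ms
      origin <- state  # snapshot: transition everyone from pre-wave states
      for (s in unique(origin)) {
        if (all(m[s, ] == 0)) {
          stop("arm '", arm, "', wave ", w, ": subjects occupy state ",
               state_bin_labels()[s], " which has no outgoing transitions")
        }
        who <- origin == s
        state[who] <- sample.int(N_STATES, sum(who), replace = TRUE,
                                 prob = m[s, ])
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject = subj, arm = arm, wave = w, huv = draw_in_bin(state))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$arm, out$subject, out$wave), ]
  rownames(out) <- NULL
  out
}

#' Generate EQ-5D responses consistent with a utility panel
#'
#' For each panel record, selects — among all possible response
#' profiles under the value set — one whose score falls in the same
#' utility bin as the record's utility, preferring the score closest to
#' the recorded value (deterministic, hence trivially reproducible).
#' Errors if some bin is unreachable under the value set.
#'
#' @param panel Data frame with columns `subject`, `arm`, `wave`, `huv`.
#' @param valueset A `value_set`.
#' @param seed Unused placeholder for API symmetry (selection is
#'   deterministic); kept so callers can thread a seed uniformly.
#' @return `panel` with added integer columns `mo, sc, ua, pd, ad`.
#' @export
generate_eq5d_responses <- function(panel, valueset = default_value_set(),
                                    seed = NULL) {
  check_panel(panel)
  nl <- valueset$n_levels
  grid <- expand.grid(mo = 1:nl, sc = 1:nl, ua = 1:nl, pd = 1:nl, ad = 1:nl)
  scores <- score_eq5d(grid, valueset)
  grid_bin <- bin_huv(pmax(scores, 0))
  target_bin <- bin_huv(panel$huv)
  unreachable <- setdiff(unique(target_bin), unique(grid_bin))
  if (length(unreachable)) {
    stop("value set cannot produce a response in utility bin(s): ",
         paste(state_bin_labels()[sort(unreachable)], collapse = ", "))
  }
  pick <- integer(nrow(panel))
  for (b in unique(target_bin)) {
    cand <- which(grid_bin == b)
    recs <- which(target_bin == b)
    # nearest candidate score to each recorded utility
    nearest <- vapply(panel$huv[recs], function(h) {
      cand[which.min(abs(scores[cand] - h))]
    }, integer(1))
    pick[recs] <- nearest
  }
  cbind(panel, grid[pick, , drop = FALSE], row.names = NULL)
}
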