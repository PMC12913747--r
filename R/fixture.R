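# Bundled reference scenario: the complete set of inputs needed to run
# the two-arm CRS model end to end. Components whose values were never
# published (entrance distribution, the medical arm's long-run decline
# matrix, the EQ-5D tariff) are synthetic stand-ins and are flagged as
# such in their file names and provenance headers.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "sinucost")
  if (p == "") stop("bundled fixture not found: ", file)
  p
}

#' Synthetic medical-arm steady-phase decline matrix
#'
#' The published year-0-to-1 matrices for both arms are improvement
#' dynamics; nothing published pins the medical arm's long-run
#' behaviour. This synthetic stand-in is the minimal structure that
#' separates the arms' long-run utilities: a near-tridiagonal decline
#' with stay 0.70, down-one-bin 0.20, up-one-bin 0.10 (bottom state:
#' stay 0.90 / up 0.10; top state: stay 0.80 / down 0.20).
#'
#' @return A `transition_matrix` (arm `"medical"`, phase `"steady"`).
#' @export
medical_decline_matrix <- function() {
  m <- matrix(0, N_STATES, N_STATES)
  for (i in 2:(N_STATES - 1)) {
    m[i, i] <- 0.70; m[i, i - 1] <- 0.20; m[i, i + 1] <- 0.10
  }
  m[1, 1] <- 0.90; m[1, 2] <- 0.10
  m[N_STATES, N_STATES] <- 0.80; m[N_STATES, N_STATES - 1] <- 0.20
  transition_matrix(m, arm = "medical", phase = "steady", normalize = FALSE)
}

#' Load the bundled reference scenario
#'
#' Returns everything needed to run the surgical-vs-medical CRS model:
#' the full parameter table, the published year-0-to-1 transition
#' matrices for both arms (transcribed as printed; their nonzero rows
#' are renormalized from rounding drift), the synthetic entrance
#' distribution, the synthetic medical steady-phase decline matrix, the
#' synthetic EQ-5D tariff, default run configuration, and ready-made
#' `strategy_model`s for both arms.
#'
#' The surgical arm uses its published matrix for all cycles; its
#' unobserved-origin rows (including state 6, reachable from state 5)
#' are patched with self-loops via [patch_unobserved_rows()] when
#' `patch_unobserved = TRUE` (default), without which the engine
#' refuses to run.
#'
#' @param patch_unobserved Patch unobserved origin rows of the surgical
#'   matrix with self-loops.
#' @param config A `model_config` stored in the fixture (default
#'   [model_config()]).
#' @return A list with components `params`, `config`, `valueset`,
#'   `entrance`, `matrices` (named list of `transition_matrix`),
#'   `medical` and `surgical` (`strategy_model`s).
#' @export
crs_fixture <- function(patch_unobserved = TRUE, config = model_config()) {
  params <- load_parameters(fixture_path("model_parameters.csv"))
  med1 <- read_transition_matrix(fixture_path("transitions_medical_year1.csv"),
                                 arm = "medical", phase = "cycle1")
  sur1 <- read_transition_matrix(fixture_path("transitions_surgical_year1.csv"),
                                 arm = "surgical", phase = "cycle1")
  med_steady <- medical_decline_matrix()
  entr_df <- utils::read.csv(fixture_path("entrance_synthetic.csv"),
                             comment.char = "#")
  entrance <- stats::setNames(entr_df$probability, entr_df$state)
  if (abs(sum(entrance) - 1) > 1e-9) stop("fixture entrance does not sum to 1")
  valueset <- read_value_set(fixture_path("valueset_synthetic.csv"))

  sur_all <- if (patch_unobserved) patch_unobserved_rows(sur1) else sur1
  medical <- strategy_model(
    arm = "medical", entrance = entrance,
    cycle1_matrix = med1, steady_matrix = med_steady,
    cost_rule = "fixed", fixed_cost_param = "cMedical",
    revision_param = 0, use_tree = FALSE)
  surgical <- strategy_model(
    arm = "surgical", entrance = entrance,
    cycle1_matrix = sur_all, steady_matrix = sur_all,
    cost_rule = "state_indexed",
    revision_param = "pRevisionESS", use_tree = TRUE)

  list(params = params, config = config, valueset = valueset,
       entrance = entrance,
       matrices = list(medical_cycle1 = med1,
                       medical_steady = med_steady,
                       surgical_cycle1 = sur_all,
                       surgical_steady = sur_all,
                       surgical_cycle1_unpatched = sur1),
       medical = medical, surgical = surgical)
}

#' Run the reference scenario end to end
#'
#' Evaluates both arms with [run_cohort()] and compares them with
#' [compute_icer()].
#'
#' @param fixture Output of [crs_fixture()].
#' @param config Overrides the fixture's `model_config` when supplied.
#' @param params Overrides the fixture's parameters when supplied (for
#'   one-way analyses).
#' @return A list with `medical` and `surgical` `cohort_result`s and
#'   the `cea_result` in `comparison`.
#' @export
evaluate_fixture <- function(fixture = crs_fixture(), config = NULL,
                             params = NULL) {
  if (is.null(config)) config <- fixture$config
  if (is.null(params)) params <- fixture$params
  med <- run_cohort(fixture$medical, config, params)
  sur <- run_cohort(fixture$surgical, config, params)
  list(medical = med, surgical = sur,
       comparison = compute_icer(med, sur))
}
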