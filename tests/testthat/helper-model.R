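# Shared fixtures for the test suite. Everything is built in code; the
# only files read are the package's own bundled CSVs.

fixture_params <- function() {
  load_parameters(system.file("extdata", "model_parameters.csv",
                              package = "sinucost"))
}

identity_matrix <- function() {
  transition_matrix(diag(10), normalize = FALSE)
}

# a cohort parked forever in one state, with no tree and no revisions
single_state_strategy <- function(state = 10, cost_rule = "state_indexed") {
  entrance <- rep(0, 10); entrance[state] <- 1
  strategy_model(arm = paste0("static", state), entrance = entrance,
                 cycle1_matrix = identity_matrix(), cost_rule = cost_rule)
}

# a small panel data frame from parallel vectors
make_panel <- function(subject, wave, huv, arm = "medical") {
  data.frame(subject = subject, arm = arm, wave = wave, huv = huv)
}
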