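test_that("an absorbing cohort reproduces the closed form exactly", {
  ps <- fixture_params()
  cfg <- model_config(discount_rate_costs = 0, discount_rate_qalys = 0)
  res <- run_cohort(single_state_strategy(10), cfg, ps)
  # 33 years at $1167/yr (healthiest-cheapest orientation) and utility 0.95
  expect_equal(res$cost, 33 * 1167, tolerance = 1e-12)
  expect_equal(res$qalys, 33 * 0.95, tolerance = 1e-12)
})

test_that("discounting follows the geometric weighting (1+r)^-(t-1)", {
  ps <- fixture_params()
  cfg <- model_config(discount_rate_costs = 0.03, discount_rate_qalys = 0.03)
  res <- run_cohort(single_state_strategy(10), cfg, ps)
  geo <- 21.3887655288  # frozen: sum(1.03^-(0:32))
  expect_equal(res$cost, 1167 * geo, tolerance = 1e-8)
  expect_equal(res$qalys, 0.95 * geo, tolerance = 1e-8)
})

test_that("a certain-death tree yields the death cost and zero QALYs", {
  ps <- set_param(fixture_params(), c(pDeath = 1))
  fx <- crs_fixture()
  res <- run_cohort(fx$surgical, fx$config, ps)
  expect_equal(res$cost, 10500 + 22548, tolerance = 1e-9)
  expect_equal(res$qalys, 0)
  expect_equal(res$death_at_entry, 1)
})

test_that("occupancy including Dead is conserved at every cycle", {
  fx <- crs_fixture()
  for (strat in list(fx$surgical, fx$medical)) {
    res <- run_cohort(strat, fx$config, fx$params)
    expect_true(all(abs(rowSums(res$trace) - 1) < 1e-10))
  }
})

test_that("the engine refuses a reachable state with no observed transitions", {
  fx <- crs_fixture(patch_unobserved = FALSE)
  unpatched <- strategy_model(
    arm = "surgical", entrance = fx$entrance,
    cycle1_matrix = fx$matrices$surgical_cycle1_unpatched,
    cost_rule = "state_indexed", use_tree = TRUE,
    revision_param = "pRevisionESS")
  # state 5 feeds state 6, whose row is all zero in the published matrix
  expect_error(run_cohort(unpatched, fx$config, fx$params), "0.5-0.599")

  bad_entry <- rep(0, 10); bad_entry[2] <- 1  # state 2 has a zero row
  expect_error(strategy_model(arm = "x", entrance = bad_entry,
                              cycle1_matrix = fx$matrices$medical_cycle1),
               "0.1-0.199")
})

test_that("microsimulation means agree with the cohort recursion within 3 SEs", {
  fx <- crs_fixture()
  strategies <- list(fx$surgical, fx$medical, single_state_strategy(8))
  for (strat in strategies) {
    coh <- run_cohort(strat, fx$config, fx$params)
    mic <- run_microsim(strat, fx$config, fx$params, n = 20000, seed = 99)
    se_c <- max(mic$se_cost, 1e-9)
    se_q <- max(mic$se_qalys, 1e-9)
    expect_lt(abs(mic$mean_cost - coh$cost), 3 * se_c)
    expect_lt(abs(mic$mean_qalys - coh$qalys), 3 * se_q)
  }
})

test_that("microsimulation is reproducible per seed", {
  fx <- crs_fixture()
  a <- run_microsim(fx$surgical, fx$config, fx$params, n = 25, seed = 5)
  b <- run_microsim(fx$surgical, fx$config, fx$params, n = 25, seed = 5)
  expect_identical(a$individuals, b$individuals)
  c2 <- run_microsim(fx$surgical, fx$config, fx$params, n = 25, seed = 6)
  expect_false(identical(a$individuals, c2$individuals))
})

test_that("QALYs and costs are monotone nonincreasing in their discount rates", {
  fx <- crs_fixture()
  rates <- c(0, 0.03, 0.06)
  runs <- lapply(rates, function(r) {
    cfg <- model_config(discount_rate_costs = r, discount_rate_qalys = r)
    run_cohort(fx$surgical, cfg, fx$params)
  })
  qalys <- vapply(runs, `[[`, numeric(1), "qalys")
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  expect_true(all(diff(qalys) < 0))
  expect_true(all(diff(costs) < 0))
})

test_that("revision risk raises costs strictly and leaves QALYs unchanged", {
  fx <- crs_fixture()
  runs <- lapply(c(0, 0.041, 0.1), function(p) {
    strat <- fx$surgical
    strat$revision_param <- p
    run_cohort(strat, fx$config, fx$params)
  })
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  qalys <- vapply(runs, `[[`, numeric(1), "qalys")
  expect_true(all(diff(costs) > 0))
  expect_equal(qalys[1], qalys[2], tolerance = 1e-12)
  expect_equal(qalys[2], qalys[3], tolerance = 1e-12)

  # no revision events appear in any trajectory when the probability is 0
  strat0 <- fx$surgical; strat0$revision_param <- 0
  mic0 <- run_microsim(strat0, fx$config, fx$params, n = 200, seed = 1)
  coh0 <- run_cohort(strat0, fx$config, fx$params)
  expect_lt(abs(mic0$mean_cost - coh0$cost), 4 * mic0$se_cost)
})

test_that("revision costing matches its expectation and sampling frequency", {
  ps <- fixture_params()
  flat_tree <- terminal_node("uncomplicated ESS", cost = 10500)
  expect_equal(apply_revision(ps, flat_tree, "expected"), 0.041 * 10500)
  ps0 <- set_param(ps, c(pRevisionESS = 0))
  expect_equal(apply_revision(ps0, flat_tree, "expected"), 0)

  set.seed(3)
  n <- 1e5
  draws <- apply_revision(ps, flat_tree, "sampled", n = n)
  p <- 0.041
  expect_lt(abs(mean(draws$revision) - p), 3 * sqrt(p * (1 - p) / n))
  expect_true(all(draws$cost[draws$revision] == 10500))
  expect_true(all(draws$cost[!draws$revision] == 0))
})

test_that("an optional background mortality vector drains the cohort", {
  ps <- fixture_params()
  entrance <- rep(0, 10); entrance[10] <- 1
  strat <- strategy_model(arm = "mort", entrance = entrance,
                          cycle1_matrix = identity_matrix(),
                          background_mortality = rep(0.1, 33))
  cfg <- model_config()
  res <- run_cohort(strat, cfg, ps)
  expect_equal(res$qalys, 0.95 * sum(0.9^(1:33)), tolerance = 1e-10)
  expect_true(all(abs(rowSums(res$trace) - 1) < 1e-10))
})
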