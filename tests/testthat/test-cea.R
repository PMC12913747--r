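test_that("ICER arithmetic and dominance classification follow the sign pattern", {
  med <- strategy_outcome("medical", 26990.27, 13.48)
  ess <- strategy_outcome("surgical", 63296.10, 22.61)
  res <- compute_icer(med, ess)
  expect_equal(res$delta_cost, 36305.83, tolerance = 1e-9)
  expect_equal(res$delta_effect, 9.13, tolerance = 1e-9)
  expect_equal(res$classification, "ICER")
  expect_equal(res$icer * res$delta_effect, res$delta_cost,
               tolerance = 1e-9)

  dominant <- compute_icer(med, strategy_outcome("s", 20000, 20))
  expect_equal(dominant$classification, "dominant")
  expect_true(is.na(dominant$icer))

  dominated <- compute_icer(med, strategy_outcome("s", 30000, 10))
  expect_equal(dominated$classification, "dominated")

  saving <- compute_icer(med, strategy_outcome("s", 20000, 10))
  expect_equal(saving$classification, "cost-saving-less-effective")
  expect_equal(saving$icer, (20000 - 26990.27) / (10 - 13.48))

  tie <- compute_icer(med, strategy_outcome("s", 30000, 13.48))
  expect_equal(tie$classification, "undefined")
  expect_true(is.na(tie$icer))
  same <- compute_icer(med, med)
  expect_equal(same$classification, "identical")
})

test_that("acceptability evaluates net monetary benefit with the tie rule", {
  s <- data.frame(delta_cost = c(100, 300, 500), delta_effect = c(1, 1, 1))
  expect_equal(ceac(s, wtp_grid = 300)$probability, 1 / 3)
  expect_equal(ceac(s, wtp_grid = 300, tie_rule = "effective")$probability,
               2 / 3)
  # lambda = 0 reduces NMB to -delta_cost
  s2 <- data.frame(delta_cost = c(-10, 5, 20), delta_effect = c(1, 1, 1))
  expect_equal(ceac(s2, wtp_grid = 0)$probability, 1 / 3)
  expect_equal(ceac(s2, wtp_grid = 1e9)$probability, 1)
  expect_error(ceac(s2, wtp_grid = c(5, 3)), "ascending")
})

test_that("acceptability is monotone in WTP when every draw gains QALYs", {
  set.seed(21)
  s <- data.frame(delta_cost = rnorm(400, 40000, 25000),
                  delta_effect = runif(400, 0.5, 9))
  curve <- ceac(s, wtp_grid = seq(0, 100000, by = 2500))
  expect_true(all(diff(curve$probability) >= 0))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
})

test_that("quadrant fractions partition the plane and bound the ray fraction", {
  s <- data.frame(delta_cost = c(10, 10, -10, -10, 50000),
                  delta_effect = c(0.5, -0.5, 0.5, -0.5, 2))
  q <- quadrant_summary(s, wtp = 10000)
  expect_equal(sum(q$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(q$fractions["I"]), 2 / 5)
  expect_equal(unname(q$fractions["II"]), 1 / 5)
  expect_equal(unname(q$fractions["IV"]), 1 / 5)
  # only the (10, 0.5) draw lies under the $10k ray; (50000, 2) sits above it
  expect_equal(q$quadrant_I_below_ray, 1 / 5)
  expect_lte(q$quadrant_I_below_ray, unname(q$fractions["I"]))

  set.seed(33)
  r <- data.frame(delta_cost = rnorm(500), delta_effect = rnorm(500))
  qr <- quadrant_summary(r, wtp = 1)
  expect_equal(sum(qr$fractions), 1, tolerance = 1e-12)
  expect_lte(qr$quadrant_I_below_ray, unname(qr$fractions["I"]))
})

test_that("one-way analysis over the surgery cost is strictly increasing", {
  fx <- crs_fixture()
  sa <- one_way_sa("cESS", 10500, 21000, steps = 3,
                   reference = fx$medical, comparator = fx$surgical,
                   params = fx$params, config = fx$config)
  expect_equal(nrow(sa), 3)
  expect_true(all(diff(sa$icer) > 0))
  expect_true(all(sa$classification == "ICER"))

  # oracle: hand-editing the parameter and re-running reproduces each point
  ps21 <- set_param(fx$params, c(cESS = 21000))
  direct <- evaluate_fixture(fx, params = ps21)$comparison
  expect_equal(sa$icer[3], direct$icer, tolerance = 1e-12)
  expect_error(one_way_sa("cNotAParam", 1, 2, steps = 2,
                          reference = fx$medical, comparator = fx$surgical,
                          params = fx$params, config = fx$config),
               "cNotAParam")
})

test_that("a degenerate (all-fixed) PSA reproduces the base case bit for bit", {
  fx <- crs_fixture()
  ps0 <- fx$params; ps0$se[] <- 0
  dists <- build_distributions(ps0)
  s <- run_psa(fx$medical, fx$surgical, fx$params, distributions = dists,
               config = fx$config, seed = 4, n = 3)
  base <- evaluate_fixture(fx)
  expect_identical(unique(s$cost_cmp), base$surgical$cost)
  expect_identical(unique(s$qalys_cmp), base$surgical$qalys)
  expect_identical(unique(s$delta_cost), base$comparison$delta_cost)
})

test_that("PSA streams are seed-reproducible and recover parameter means", {
  fx <- crs_fixture()
  a <- run_psa(fx$medical, fx$surgical, fx$params, config = fx$config,
               seed = 17, n = 40)
  b <- run_psa(fx$medical, fx$surgical, fx$params, config = fx$config,
               seed = 17, n = 40)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "parameter_draws"), attr(b, "parameter_draws"))

  n <- 2000
  s <- run_psa(fx$medical, fx$surgical, fx$params, config = fx$config,
               seed = 18, n = n)
  draws <- attr(s, "parameter_draws")
  # parameters outside complement groups keep their published moments
  for (nm in c("pDeath", "pRevisionESS", "cMarkov1", "cMarkov10")) {
    mu <- fx$params$mean[fx$params$name == nm]
    se <- fx$params$se[fx$params$name == nm]
    expect_lt(abs(mean(draws[, nm]) - mu), 3 * se / sqrt(n))
  }
  expect_true(all(s$delta_effect > 0))
})
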