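test_that("a complete parameter table loads with its published values intact", {
  ps <- fixture_params()
  expect_s3_class(ps, "parameter_set")
  expect_equal(unname(param_value(ps, "pRevisionESS")), 0.041)
  expect_equal(ps$se[ps$name == "pRevisionESS"], 0.005)
  expect_equal(unname(param_value(ps, "cESS")), 10500)
  expect_equal(unname(param_value(ps, "cMedical")), 772)
  # blank se reads as a fixed parameter
  expect_equal(ps$se[ps$name == "cESS"], 0)
  # complementary intraoperative pair renormalized from its printed sum 0.9999
  expect_equal(unname(param_value(ps, "pIntraOpComp")), 0.0095 / 0.9999)
  expect_equal(sum(param_value(ps, c("pIntraOpComp", "pNoIntraOpComp"))), 1)
})

test_that("incomplete or out-of-domain tables are rejected with named errors", {
  ps <- fixture_params()
  broken <- as.data.frame(ps)[ps$name != "cESS", ]
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken[, c("name", "description", "mean", "se", "source")],
            path, row.names = FALSE)
  expect_error(load_parameters(path), "cESS")

  bad <- as.data.frame(ps)
  bad$mean[bad$name == "pDeath"] <- 1.5
  write.csv(bad[, c("name", "description", "mean", "se", "source")],
            path, row.names = FALSE)
  expect_error(load_parameters(path), "pDeath")

  # complementary group far from 1 is an error, not a silent rescale
  worse <- as.data.frame(ps)
  worse$mean[worse$name == "pPostOpComp"] <- 0.10
  expect_error(parameter_set(worse), "complementary")
})

test_that("beta moment matching reproduces its targets and rejects infeasible moments", {
  # uniform distribution: mean 1/2, variance 1/12
  unif <- beta_from_moments(0.5, sqrt(1 / 12))
  expect_equal(unif$shape1, 1, tolerance = 1e-9)
  expect_equal(unif$shape2, 1, tolerance = 1e-9)
  # frozen hand arithmetic: nu = m(1-m)/se^2 - 1 = 2999.939088
  spec <- beta_from_moments(0.1727, 0.0069)
  expect_equal(spec$shape1, 518.089481, tolerance = 1e-6)
  expect_equal(spec$shape2, 2481.849608, tolerance = 1e-6)

  for (case in list(c(0.0001, 3e-05), c(0.041, 0.005), c(0.73, 0.069))) {
    mom <- spec_moments(beta_from_moments(case[1], case[2]))
    expect_equal(unname(mom["mean"]), case[1], tolerance = 1e-9)
    expect_equal(unname(mom["sd"]), case[2], tolerance = 1e-9)
  }
  expect_error(beta_from_moments(0.5, 0.8), "infeasible")
  expect_error(beta_from_moments(0, 0.1), "mean")
})

test_that("gamma moment matching reproduces its targets and rejects bad domains", {
  # se equal to mean collapses to shape 1 (an exponential)
  exp1 <- gamma_from_moments(1167, 1167)
  expect_equal(exp1$shape, 1, tolerance = 1e-12)
  expect_equal(exp1$scale, 1167, tolerance = 1e-12)
  g <- gamma_from_moments(100, 10)
  expect_equal(g$shape, 100, tolerance = 1e-12)
  expect_equal(g$scale, 1, tolerance = 1e-12)
  for (case in list(c(10500, 500), c(772, 80), c(22548, 22548))) {
    mom <- spec_moments(gamma_from_moments(case[1], case[2]))
    expect_equal(unname(mom["mean"]), case[1], tolerance = 1e-9)
    expect_equal(unname(mom["sd"]), case[2], tolerance = 1e-9)
  }
  expect_error(gamma_from_moments(0, 5), "mean")
  expect_error(gamma_from_moments(100, 0), "se")
})

test_that("sampling a constructed spec reproduces the target moments", {
  n <- 1e5
  set.seed(42)
  for (spec in list(beta_from_moments(0.1727, 0.0069),
                    beta_from_moments(0.73, 0.069),
                    gamma_from_moments(1167, 1167))) {
    x <- sample_spec(spec, n)
    expect_lt(abs(mean(x) - spec$mean), 3 * spec$se / sqrt(n))
    expect_lt(abs(sd(x) - spec$se) / spec$se, 0.02)
  }
})

test_that("distribution assignment follows parameter kind and fixes se = 0", {
  ps <- fixture_params()
  expect_warning(dists <- build_distributions(ps), "cMarkov")
  expect_equal(dists$pRevisionESS$family, "beta")
  expect_equal(dists$cMarkov1$family, "gamma")
  expect_equal(dists$cMarkov1$shape, 1)
  expect_equal(dists$cESS$family, "fixed")
  expect_equal(sample_spec(dists$cESS, 3), rep(10500, 3))
})

test_that("complement groups are reported with their raw deviations", {
  raw <- load_parameters(system.file("extdata", "model_parameters.csv",
                                     package = "sinucost"),
                         renormalize = FALSE)
  rep <- validate_complement_pairs(raw, tol = 0.001)
  intra <- rep[rep$group == "intraop", ]
  expect_equal(intra$deviation, 1e-4, tolerance = 1e-9)
  expect_false(intra$flagged)
  # the three-way postoperative type split sums to 1 as printed
  expect_equal(rep$deviation[rep$group == "postop_type"], 0, tolerance = 1e-12)

  off <- set_param(raw, c(pPostOpEpistaxisCons = 0.17), renormalize = FALSE)
  rep2 <- validate_complement_pairs(off, tol = 0.01)
  expect_true(rep2$flagged[rep2$group == "epistaxis"])
})

test_that("write/read round trip is the identity", {
  ps <- fixture_params()
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameters(ps, path)
  back <- load_parameters(path)
  expect_equal(as.data.frame(back), as.data.frame(ps))
})
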