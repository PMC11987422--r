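test_that("random treatment assignment is seeded Bernoulli with the right rate", {
  t1 <- assign_random_treatment(10, seed = 4)
  t2 <- assign_random_treatment(10, seed = 4)
  expect_identical(t1, t2)
  expect_true(all(t1 %in% c(0, 1)))

  big <- assign_random_treatment(1e5, p = 0.5, seed = 1)
  expect_lt(abs(mean(big) - 0.5), 0.01)

  expect_error(assign_random_treatment(10, p = 1), "p must")

  # independence from any outcome: correlation within +-3/sqrt(n)
  set.seed(2)
  n <- 5e4
  y <- rbinom(n, 1, 0.3)
  tr <- assign_random_treatment(n, seed = 3)
  expect_lt(abs(cor(tr, y)), 3 / sqrt(n))
})

test_that("the prognostic model discriminates when and only when outcomes carry signal", {
  set.seed(14)
  n <- 3000
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y_noise <- rbinom(n, 1, 0.3)
  fit <- fit_prognostic_model(dat, y_noise, c("x1", "x2"))
  expect_lt(abs(fit$auc - 0.5), 0.05)

  # severity-driven composite outcome on the generated cohort
  fx <- small_fixture()
  prog <- fit_prognostic_model(fx$cohort, fx$cohort$outcome_composite,
                               c("age", "sex", measured_confounder_names()))
  expect_gt(prog$auc, 0.8)

  # predictions agree with an independent Newton fit
  oracle_beta <- irls_oracle(as.matrix(dat), y_noise)
  oracle_pred <- plogis(cbind(1, as.matrix(dat)) %*% oracle_beta)
  expect_equal(fit$scores, as.numeric(oracle_pred), tolerance = 1e-6)

  expect_error(fit_prognostic_model(dat, rep(1, n), c("x1", "x2")),
               "degenerate")
})

test_that("quartile bins cut at empirical quartiles with ties going down", {
  b <- quartile_bins(1:8)
  expect_equal(as.integer(table(b)), rep(2L, 4))
  expect_equal(as.character(b[1:2]), c("Q1", "Q1"))

  expect_warning(b2 <- quartile_bins(rep(3.7, 10)), "collapsed")
  expect_true(all(b2 == "Q1"))

  set.seed(10)
  b3 <- quartile_bins(runif(103))
  expect_lte(diff(range(table(b3))), 3)
})

test_that("the scenario grid interpolates exactly between the printed extremes", {
  g <- scenario_grid(10)
  expect_equal(nrow(g), 10L)
  expect_equal(as.numeric(g[1, c("w1", "w2", "w3", "w4")]),
               c(0.4, 0.3, 0.2, 0.1))
  expect_equal(as.numeric(g[10, c("w1", "w2", "w3", "w4")]),
               c(0.1, 0.2, 0.3, 0.4))
  expect_equal(rowSums(g[, c("w1", "w2", "w3", "w4")]),
               rep(1, 10), tolerance = 1e-15, ignore_attr = TRUE)

  mid <- scenario_grid(3)[2, ]
  expect_equal(as.numeric(mid[, c("w1", "w2", "w3", "w4")]), rep(0.25, 4))
  expect_error(scenario_grid(1), "n_scenarios")
})

test_that("scenario sampling realises the requested quartile composition exactly", {
  set.seed(33)
  n <- 12000
  tr <- rbinom(n, 1, 0.5)
  bins <- quartile_bins(runif(n))

  s <- sample_simulation_cohort(tr, bins, c(0.25, 0.25, 0.25, 0.25),
                                n_control = 1000, n_treated = 400, seed = 1)
  bk <- s$bookkeeping
  expect_equal(bk$requested[bk$arm == "treated"], rep(100, 4))
  expect_equal(bk$realised, bk$requested)

  s2 <- sample_simulation_cohort(tr, bins, c(0.4, 0.3, 0.2, 0.1),
                                 n_control = 1000, n_treated = 1000, seed = 1)
  bk2 <- s2$bookkeeping
  expect_equal(bk2$requested[bk2$arm == "treated"], c(400, 300, 200, 100))
  expect_equal(bk2$realised, bk2$requested)
  # without replacement: no duplicated units, sizes exact
  expect_false(any(duplicated(s2$idx)))
  expect_equal(sum(s2$treatment), 1000L)
  expect_equal(sum(s2$treatment == 0), 1000L)

  expect_error(
    sample_simulation_cohort(tr, bins, c(0.97, 0.01, 0.01, 0.01),
                             n_control = 100, n_treated = 4000, seed = 1),
    "quartile Q1")
})

test_that("the simulation loop keeps per-replicate bookkeeping and is seed-stable", {
  fx <- small_fixture()
  sim <- suppressMessages(run_simulation(
    fx$features, fx$specs, scenarios = scenario_grid(5)[3, ], n_reps = 2,
    n_control = 400, n_treated = 400, n_boot = 50, seed = 17))
  expect_equal(nrow(sim$replicates), 2L * 4L)
  expect_setequal(unique(sim$replicates$model), 1:4)
  expect_equal(sort(unique(sim$replicates$rep)), 1:2)
  expect_true(all(sim$replicates$covered %in% c(TRUE, FALSE)))

  sim2 <- suppressMessages(run_simulation(
    fx$features, fx$specs, scenarios = scenario_grid(5)[3, ], n_reps = 2,
    n_control = 400, n_treated = 400, n_boot = 50, seed = 17))
  expect_equal(sim$replicates, sim2$replicates)
})

test_that("a uniform sampling scenario injects no confounding", {
  fx <- small_fixture()
  sim <- suppressMessages(run_simulation(
    fx$features, list(fx$specs$m1, fx$specs$m2),
    scenarios = scenario_grid(3)[2, ], n_reps = 6,
    n_control = 600, n_treated = 600, n_boot = 50, seed = 23))
  m1 <- sim$summary[sim$summary$model == 1, ]
  # truth is 0; Monte-Carlo error of a median of 6 reps at n = 1200
  expect_lt(abs(m1$median_estimate), 0.05)
})

test_that("coverage counts intervals containing the truth", {
  reps <- tibble::tibble(lower = c(-1, 0.2, -0.5), upper = c(1, 0.4, -0.1))
  expect_equal(coverage(reps), 1 / 3)
  expect_equal(coverage(tibble::tibble(lower = -1, upper = 1)), 1)
  expect_equal(coverage(tibble::tibble(lower = c(0.1, 0.3),
                                       upper = c(0.2, 0.5))), 0)
  # brute-force recount on a random replicate list
  set.seed(2)
  lo <- rnorm(50); hi <- lo + runif(50)
  reps2 <- tibble::tibble(lower = lo, upper = hi)
  expect_equal(coverage(reps2), sum(lo <= 0 & hi >= 0) / 50)
  expect_error(coverage(reps2[0, ]), "no replicates")
})
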