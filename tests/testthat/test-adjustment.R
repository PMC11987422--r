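test_that("model specifications enforce the four-model structure", {
  expect_error(model_spec(1, "age"), "no covariates")
  expect_error(model_spec(2), "at least one")
  expect_error(model_spec(5, "age"), "model_id")
  specs <- default_model_specs(c("jcs", "sbp"), paste0("v", 1:3))
  expect_equal(specs$m1$covariates, character())
  expect_setequal(specs$m3$covariates, c("age", "sex", paste0("v", 1:3)))
  expect_setequal(specs$m4$covariates,
                  union(specs$m2$covariates, specs$m3$covariates))
})

test_that("propensity fits reduce to the treated fraction for uninformative covariates", {
  set.seed(1)
  dat <- data.frame(x = rep(1, 200))
  tr <- rep(c(1, 0), c(60, 140))
  fit <- fit_propensity(dat, tr, model_spec(2, "x"))
  expect_equal(fit$ps, rep(0.3, 200), tolerance = 1e-8)
})

test_that("separation triggers the ridge fallback (or an error when disabled)", {
  dat <- data.frame(x = rep(c(1, 0), each = 30))
  tr <- dat$x
  expect_error(fit_propensity(dat, tr, model_spec(2, "x"),
                              ridge_fallback = FALSE), "separation")
  fit <- suppressMessages(fit_propensity(dat, tr, model_spec(2, "x")))
  expect_true(fit$separation)
  expect_true(all(fit$ps[tr == 1] > 0.95))
  expect_true(all(fit$ps[tr == 0] < 0.05))
})

test_that("maximum-likelihood coefficients match an independent Newton fit", {
  set.seed(77)
  n <- 200
  X <- cbind(age = rnorm(n, 70, 8), sev = rnorm(n), bin = rbinom(n, 1, 0.4))
  tr <- rbinom(n, 1, plogis(-0.3 + 0.04 * (X[, 1] - 70) + 0.8 * X[, 2]))
  dat <- as.data.frame(X)
  fit <- fit_propensity(dat, tr, model_spec(2, colnames(X)))
  oracle <- irls_oracle(X, tr)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-6)
})

test_that("nearest-neighbour matching picks the closest control within the caliper", {
  ps <- c(0.5, 0.5, 0.9)
  tr <- c(1, 0, 0)
  mc <- match_cohort(ps, tr, caliper_fraction = 10, seed = 1)
  expect_equal(nrow(mc), 1L)
  expect_equal(mc$control, 2L)

  # all controls outside the caliper -> zero pairs is an error
  ps2 <- c(0.10, 0.90, 0.95)
  expect_error(match_cohort(ps2, c(1, 0, 0), caliper_fraction = 0.01,
                            seed = 1), "zero matched pairs")
})

test_that("matching satisfies the caliper exactly and is 1:1 without replacement", {
  set.seed(12)
  ps <- runif(300)
  tr <- rbinom(300, 1, 0.4)
  mc <- match_cohort(ps, tr, caliper_fraction = 0.5, seed = 4)
  expect_lte(max(abs(mc$ps_treated - mc$ps_control)), attr(mc, "caliper"))
  expect_false(any(duplicated(mc$control)))
  expect_false(any(duplicated(mc$treated)))
  expect_equal(nrow(mc) + attr(mc, "n_unmatched"), sum(tr == 1))
})

test_that("matching replays the brute-force greedy algorithm", {
  set.seed(5)
  ps <- runif(100)
  tr <- rbinom(100, 1, 0.5)
  mc <- match_cohort(ps, tr, caliper_fraction = 0.3, seed = 11)
  oracle <- greedy_match_oracle(ps, tr, caliper_fraction = 0.3, seed = 11)
  expect_equal(mc$treated, unname(oracle[, "treated"]))
  expect_equal(mc$control, unname(oracle[, "control"]))
})

test_that("standardised mean differences follow the pooled-SD formula", {
  expect_equal(smd(c(1, 2, 3, 1, 2, 3), rep(c(1, 0), each = 3)), 0)
  # means 1 vs 0, both SD 1
  expect_equal(smd(c(0, 1, 2, -1, 0, 1), rep(c(1, 0), each = 3)), 1.0)

  set.seed(9)
  v <- rnorm(50)
  tr <- rbinom(50, 1, 0.5)
  expect_equal(smd(v, tr), smd_oracle(v, tr), tolerance = 1e-12)

  b <- rbinom(50, 1, 0.3)
  expect_equal(smd(b, tr), smd_oracle(b, tr), tolerance = 1e-12)

  expect_error(smd(v, rep(1, 50)), "nonempty")
  expect_warning(z <- smd(rep(c(1, 2), each = 5), rep(c(1, 0), each = 5)),
                 "undefined")
  expect_true(is.na(z))
})

test_that("smd restricted to matched pairs uses matched units only", {
  set.seed(21)
  ps <- runif(200)
  tr <- rbinom(200, 1, 0.5)
  v <- rnorm(200) + tr
  mc <- match_cohort(ps, tr, caliper_fraction = 1, seed = 2)
  manual <- smd_oracle(c(v[mc$treated], v[mc$control]),
                       rep(c(1, 0), each = nrow(mc)))
  expect_equal(smd(v, tr, matched = mc), manual, tolerance = 1e-12)
})

test_that("the c-statistic equals brute-force concordant-pair counting", {
  set.seed(3)
  scores <- sample(1:10, 40, replace = TRUE) # ties on purpose
  y <- rbinom(40, 1, 0.5)
  expect_equal(cstat(scores, y), auc_pairs_oracle(scores, y))
  expect_equal(cstat(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_error(cstat(1:5, rep(1, 5)), "both label classes")

  # independent library cross-check
  expect_equal(cstat(scores, y),
               as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE))))
})

test_that("matched c-statistic approaches 0.5 for noise covariates and 1 under separation", {
  set.seed(41)
  n <- 2000
  dat <- data.frame(noise1 = rnorm(n), noise2 = rnorm(n))
  tr <- rbinom(n, 1, 0.5)
  ps <- runif(n)
  mc <- match_cohort(ps, tr, caliper_fraction = 5, seed = 3)
  cs <- matched_cstat(mc, dat, tr, model_spec(2, c("noise1", "noise2")))
  expect_lt(abs(cs - 0.5), 0.05)

  # a covariate that separates treatment in the matched set
  dat$sep <- tr
  cs1 <- suppressMessages(matched_cstat(mc, dat, tr, model_spec(2, "sep")))
  expect_equal(cs1, 1.0)
})

test_that("effect estimates match closed-form differences with sane CIs", {
  expect_equal(estimate_effect(rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(5, 5)),
                               n_boot = 50, seed = 1)$estimate, 1.0)

  est0 <- estimate_effect(rep(c(1, 0, 1, 0), 10), rep(c(1, 1, 0, 0), 10),
                          n_boot = 200, seed = 1)
  expect_equal(est0$estimate, 0)
  expect_lte(est0$lower, 0)
  expect_gte(est0$upper, 0)

  # 2x2 table (a, b, c, d): RD = a/(a+b) - c/(c+d)
  a <- 12; b <- 18; c <- 7; d <- 23
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  tr <- rep(c(1, 0), c(a + b, c + d))
  est <- estimate_effect(y, tr, n_boot = 100, seed = 2)
  expect_equal(est$estimate, a / (a + b) - c / (c + d), tolerance = 1e-12)
  expect_equal(est$estimand, "risk difference")

  expect_error(estimate_effect(y, tr, n_boot = 1), "n_boot")

  # continuous outcomes yield a mean difference
  lo <- estimate_effect(rnorm(60, mean = 2), rbinom(60, 1, 0.5),
                        n_boot = 50, seed = 3)
  expect_equal(lo$estimand, "mean difference")

  # seeded bootstrap is reproducible
  e1 <- estimate_effect(y, tr, n_boot = 100, seed = 9)
  e2 <- estimate_effect(y, tr, n_boot = 100, seed = 9)
  expect_identical(e1, e2)
})

test_that("matched estimation operates on pair differences", {
  set.seed(6)
  ps <- runif(200)
  tr <- rbinom(200, 1, 0.5)
  y <- rbinom(200, 1, 0.3)
  mc <- match_cohort(ps, tr, caliper_fraction = 5, seed = 8)
  est <- estimate_effect(y, tr, matched = mc, n_boot = 100, seed = 1)
  expect_equal(est$estimate, mean(y[mc$treated]) - mean(y[mc$control]),
               tolerance = 1e-12)
  expect_equal(est$n, nrow(mc))
})
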