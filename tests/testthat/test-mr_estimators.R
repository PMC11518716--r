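test_that("the Wald ratio and its delta-method se follow the formula", {
  inst <- make_insts(0.1, 0.05, se_exp = 0.02, se_out = 0.01)
  fit <- wald_ratio(inst)
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$se,
               sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.02^2 / 0.1^4))
  expect_equal(wald_ratio(make_insts(0.1, 0))$beta, 0)
  expect_error(wald_ratio(make_insts(0, 0.05)), "undefined")
  # scaling the exposure by c scales the estimate by 1/c
  expect_equal(wald_ratio(make_insts(0.2, 0.05, se_exp = 0.04,
                                     se_out = 0.01))$beta, 0.25)
})

test_that("IVW pools ratios by inverse variance", {
  insts <- insts_from_ratios(c(0.4, 0.6), c(0.1, 0.1))
  fit <- ivw(insts, mode = "fixed")
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$se, 1 / sqrt(1 / 0.01 + 1 / 0.01))
  # homogeneous ratios: Q = 0, random-effects se equals fixed se
  homog <- insts_from_ratios(c(0.7, 0.7, 0.7), c(0.1, 0.2, 0.3))
  expect_equal(ivw(homog, "random")$beta, 0.7)
  expect_equal(ivw(homog, "random")$se, ivw(homog, "fixed")$se)
  expect_error(ivw(insts[1, ]), "wald_ratio")
})

test_that("IVW equals origin-constrained WLS on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:40, 1)
    insts <- make_insts(beta_exp = rnorm(n, 0.1, 0.05),
                        beta_out = rnorm(n, 0.03, 0.05),
                        se_exp = runif(n, 0.005, 0.03),
                        se_out = runif(n, 0.01, 0.2))
    insts <- insts[abs(insts$beta_exp) > 1e-3, ]
    fit <- ivw(insts, mode = "fixed")
    wls <- stats::lm(beta_out ~ 0 + beta_exp, data = insts,
                     weights = 1 / insts$se_out^2)
    expect_equal(fit$beta, unname(coef(wls)), tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers an exact affine relation", {
  insts <- make_insts(beta_exp = c(0.05, 0.10, 0.20),
                      beta_out = 0.1 + 2 * c(0.05, 0.10, 0.20),
                      se_out = c(0.1, 0.15, 0.2))
  fit <- mr_egger(insts)
  expect_equal(fit$result$beta, 2)
  expect_equal(fit$intercept$value, 0.1)
  expect_error(mr_egger(insts[1:2, ]), ">= 3")
})

test_that("MR-Egger is invariant to instrument sign orientation", {
  set.seed(9)
  insts <- make_insts(beta_exp = rnorm(10, 0.1, 0.08),
                      beta_out = rnorm(10, 0.05, 0.05),
                      se_out = runif(10, 0.05, 0.2))
  flipped <- insts
  flipped$beta_exp[1:4] <- -flipped$beta_exp[1:4]
  flipped$beta_out[1:4] <- -flipped$beta_out[1:4]
  expect_equal(mr_egger(flipped)$result$beta, mr_egger(insts)$result$beta)
})

test_that("the weighted median interpolates cumulative weight midpoints", {
  eq <- insts_from_ratios(c(0.1, 0.2, 0.9), c(1, 1, 1))
  expect_equal(weighted_median(eq, n_boot = 10, seed = 1)$beta, 0.2)
  # the middle ratio holds >= 50% of the weight exactly at its midpoint
  maj <- insts_from_ratios(c(0.1, 0.2, 0.9),
                           1 / sqrt(c(0.2, 0.6, 0.2)))
  expect_equal(weighted_median(maj, n_boot = 10, seed = 1)$beta, 0.2)
  # same seed, same bootstrap se
  a <- weighted_median(eq, n_boot = 50, seed = 7)
  b <- weighted_median(eq, n_boot = 50, seed = 7)
  expect_identical(a$se, b$se)
  expect_error(weighted_median(eq[1:2, ]), ">= 3")
})

test_that("mode estimators find the dominant ratio cluster", {
  degen <- insts_from_ratios(rep(0.5, 4), rep(0.1, 4))
  expect_equal(mode_estimator(degen, "simple", n_boot = 5, seed = 1)$beta,
               0.5)
  mixed <- insts_from_ratios(c(0.5, 0.5, 0.5, 0.5, 2.0), rep(0.1, 5))
  est <- mode_estimator(mixed, "simple", n_boot = 5, seed = 1)$beta
  expect_lt(abs(est - 0.5), 0.15)
  w_est <- mode_estimator(mixed, "weighted", n_boot = 5, seed = 1)$beta
  expect_lt(abs(w_est - 0.5), 0.15)
  a <- mode_estimator(mixed, "weighted", n_boot = 50, seed = 3)
  b <- mode_estimator(mixed, "weighted", n_boot = 50, seed = 3)
  expect_identical(a$se, b$se)
})

test_that("run_all_methods composes the five-estimator suite", {
  truth <- simulation_truth(theta = 0.3, seed = 61)
  panel <- simulate_gwas_panel(truth)
  insts <- harmonize(panel$exposure, panel$outcomes$primary)$instruments
  res <- run_all_methods(insts, seed = 1, n_boot = 100)
  expect_setequal(res$method, c("ivw_random", "mr_egger", "weighted_median",
                                "simple_mode", "weighted_mode"))
  expect_equal(attr(res, "primary"), "ivw_random")
  # determinism end to end
  res2 <- run_all_methods(insts, seed = 1, n_boot = 100)
  expect_equal(res, res2, ignore_attr = TRUE)

  two <- run_all_methods(insts[1:2, ], seed = 1, n_boot = 10)
  expect_equal(two$method, "ivw_random")
  expect_true("mr_egger" %in% attr(two, "skipped")$method)

  one <- run_all_methods(insts[1, ], seed = 1)
  expect_equal(one$method, "wald_ratio")
})

test_that("odds-ratio mapping is monotone and brackets the estimate", {
  r1 <- ivw(insts_from_ratios(c(0.2, 0.3, 0.4), rep(0.1, 3)))
  r2 <- ivw(insts_from_ratios(c(0.5, 0.6, 0.7), rep(0.1, 3)))
  expect_lt(r1$or_value, r2$or_value)
  expect_true(r1$ci_low < r1$or_value && r1$or_value < r1$ci_high)
})
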