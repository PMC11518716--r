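test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_fdr(rep(0.37, 6)), rep(0.37, 6))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\(0, 1\\]")
  for (seed in 1:25) {
    set.seed(seed)
    p <- runif(sample(2:200, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("tiers partition exposures by FDR and raw p", {
  expect_equal(assign_tier(0.0001, 0.032), "significant")
  expect_equal(assign_tier(0.0029, 0.230), "suggestive")
  expect_equal(assign_tier(0.2, 0.8), "null")
  # vectorized, exactly one tier each
  tiers <- assign_tier(c(0.001, 0.02, 0.5), c(0.01, 0.2, 0.9))
  expect_equal(tiers, c("significant", "suggestive", "null"))
})

test_that("fixed-effect meta-analysis pools by inverse variance", {
  r1 <- data.frame(beta = 0.8, se = 0.2)
  r2 <- data.frame(beta = 0.5, se = 0.4)
  m <- meta_fixed(r1, r2)
  w <- c(1 / 0.04, 1 / 0.16)
  expect_equal(m$beta_combined, sum(w * c(0.8, 0.5)) / sum(w))
  expect_equal(m$beta_combined, 0.74)
  expect_equal(m$se_combined, 1 / sqrt(sum(w)))
  expect_equal(m$se_combined, 0.17888544, tolerance = 1e-7)

  # identical inputs: same estimate, se shrinks by sqrt(2)
  m2 <- meta_fixed(r1, r1)
  expect_equal(m2$beta_combined, 0.8)
  expect_equal(m2$se_combined, 0.2 / sqrt(2))

  # one arm with enormous uncertainty contributes nothing
  m3 <- meta_fixed(r1, data.frame(beta = -5, se = 1e8))
  expect_equal(m3$beta_combined, 0.8, tolerance = 1e-10)

  # information is never lost
  expect_lt(m$se_combined, min(r1$se, r2$se))
})

test_that("meta-analysis agrees with an established meta-analysis fit", {
  skip_if_not_installed("metafor")
  set.seed(91)
  for (i in 1:5) {
    b <- rnorm(2, 0.3, 0.5)
    s <- runif(2, 0.05, 0.5)
    m <- meta_fixed(data.frame(beta = b[1], se = s[1]),
                    data.frame(beta = b[2], se = s[2]))
    ref <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(m$beta_combined, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(m$se_combined, ref$se, tolerance = 1e-10)
  }
})

test_that("meta-analysis refuses mismatched scales", {
  r1 <- data.frame(beta = 0.8, se = 0.2, scale = "log_odds")
  r2 <- data.frame(beta = 0.5, se = 0.4, scale = "sd_units")
  expect_error(meta_fixed(r1, r2), "scale mismatch")
})

test_that("direction consistency requires matching nonzero signs", {
  expect_true(direction_consistency(0.8, 0.5))
  expect_false(direction_consistency(0.8, -0.1))
  expect_false(direction_consistency(0.0, 0.5))
  expect_true(direction_consistency(data.frame(beta = -1),
                                    data.frame(beta = -2)))
})

test_that("panel screening tiers, replicates and flags candidates", {
  primary <- data.frame(
    exposure_id = c("m1", "m2", "m3", "m4"),
    n_snp = 10L,
    beta = c(0.6, 0.5, 0.4, 0.01),
    se = c(0.1, 0.1, 0.1, 0.1),
    pvalue = c(2e-9, 6e-7, 6e-5, 0.92),
    stringsAsFactors = FALSE)
  replication <- data.frame(
    exposure_id = c("m1", "m2"),
    n_snp = 10L,
    beta = c(0.5, -0.45),
    se = c(0.15, 0.15),
    pvalue = c(9e-4, 0.003),
    stringsAsFactors = FALSE)
  out <- screen_panel(primary, replication)
  expect_equal(out$fdr_value, bh_fdr(primary$pvalue))
  expect_equal(sum(out$tier == "null"), 1)
  # every exposure gets exactly one tier
  expect_true(all(out$tier %in% c("significant", "suggestive", "null")))

  # m1 replicates with the same sign and a significant meta p
  expect_true(out$candidate[out$exposure_id == "m1"])
  # m2 flips sign: excluded regardless of meta p
  m2 <- out[out$exposure_id == "m2", ]
  expect_false(m2$direction_consistent)
  expect_false(m2$candidate)
  expect_lt(m2$pvalue_meta, 0.05)
  # m3 has no replication: meta fields empty, flag withheld
  m3 <- out[out$exposure_id == "m3", ]
  expect_true(is.na(m3$pvalue_meta))
  expect_false(m3$candidate)
})
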