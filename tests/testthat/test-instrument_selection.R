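rec_at <- function(snp_id, pos, pvalue, chrom = "1") {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = "A", other_allele = "G", eaf = 0.3,
             beta = 0.1, se = 0.02, pvalue = pvalue, n_samples = 7824,
             stringsAsFactors = FALSE)
}

test_that("the p-value filter keeps exactly the sub-threshold records", {
  rec <- rec_at(c("a", "b", "c"), c(1, 2, 3) * 1e5, c(1e-6, 2e-5, 1e-8))
  expect_equal(filter_by_pvalue(rec, 1e-5)$snp_id, c("a", "c"))
  expect_equal(nrow(filter_by_pvalue(rec, 1)), 3)
  expect_equal(nrow(filter_by_pvalue(rec[0, ], 1e-5)), 0)
})

test_that("clumping keeps the best hit per correlated window", {
  rec <- rec_at(c("A", "B", "C"), c(100000, 150000, 500000),
                c(1e-8, 1e-6, 1e-7))
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.5
  r2[1, 3] <- r2[3, 1] <- 0.001
  ld <- ld_matrix(c("A", "B", "C"), r2)
  kept <- clump(rec, ld, clump_r2 = 0.01, clump_kb = 100)
  expect_equal(kept$snp_id, c("A", "C"))
  expect_equal(attr(kept, "removed")$snp_id, "B")

  # independence: nothing is removed
  expect_equal(clump(rec, ld_matrix(rec$snp_id, diag(3)), 0.01, 100)$snp_id,
               rec$snp_id)

  # perfect LD at the same locus: only the smaller-p SNP survives
  rec2 <- rec_at(c("x", "y"), c(1000, 1000), c(1e-6, 1e-9))
  r2 <- matrix(1, 2, 2)
  expect_equal(clump(rec2, ld_matrix(c("x", "y"), r2), 0.01, 100)$snp_id, "y")
})

test_that("a record missing from the LD matrix is a named hard error", {
  rec <- rec_at(c("a", "zz"), c(1, 2) * 1e5, c(1e-6, 1e-7))
  expect_error(clump(rec, ld_matrix("a", diag(1)), 0.01, 100), "zz")
})

test_that("clumping equals the exhaustive greedy oracle on random panels", {
  for (seed in 1:4) {
    n <- c(50, 120, 200, 200)[seed]
    panel <- random_panel(n, seed)
    mine <- clump(panel$records, panel$ld, clump_r2 = 0.05, clump_kb = 250)
    ref <- oracle_clump(panel$records, panel$ld, 0.05, 250)
    expect_equal(mine$snp_id, ref$snp_id)
    # retained pairs within the window never exceed the r2 cap
    for (i in seq_len(nrow(mine))) {
      same <- mine$chrom == mine$chrom[i] &
        abs(mine$pos - mine$pos[i]) <= 250000 & mine$snp_id != mine$snp_id[i]
      if (any(same)) {
        expect_true(all(panel$ld[mine$snp_id[i], mine$snp_id[same]] <= 0.05))
      }
    }
  }
})

test_that("the F-statistic follows the variance-explained formula", {
  # R2 = 2*0.5*0.5*0.2^2 = 0.02 at maf 0.5, standardized beta 0.2
  rec <- rec_at("a", 1000, 1e-8)
  rec$eaf <- 0.5
  rec$beta <- 0.2
  out <- f_statistic(rec, n_samples = 7824, sd_trait = 1)
  expect_equal(out$r_squared, 0.02)
  expect_equal(out$f_value, 0.02 * (7824 - 2) / (0.98 * 1))

  rec$beta <- 0
  expect_equal(f_statistic(rec, sd_trait = 1)$f_value, 0)

  # monotone in N for fixed R2, K
  rec$beta <- 0.2
  f1 <- f_statistic(rec, n_samples = 1000, sd_trait = 1)$f_value
  f2 <- f_statistic(rec, n_samples = 10000, sd_trait = 1)$f_value
  expect_gt(f2, f1)
})

test_that("F-statistic guards its preconditions", {
  rec <- rec_at("a", 1000, 1e-8)
  rec$eaf <- NA
  expect_error(f_statistic(rec, sd_trait = 1), "missing eaf")
  rec$eaf <- 0.5
  rec$beta <- 3 # R2 = 4.5 >= 1
  expect_error(f_statistic(rec, sd_trait = 1), "malformed")
})

test_that("the z-score approximation is close for strong instruments", {
  truth <- simulation_truth(seed = 11)
  ex <- simulate_exposure_stats(truth)
  exact <- f_statistic(ex, sd_trait = 1)$f_value
  approx <- suppressMessages(f_statistic(ex)$f_value)
  expect_equal(approx, exact, tolerance = 0.2)
})

test_that("confounder exclusion matches trait labels case-insensitively", {
  rec <- rec_at(c("rs1", "rs2", "rs3"), c(1, 2, 3) * 1e5, rep(1e-8, 3))
  ann <- data.frame(snp_id = c("rs1", "rs2"),
                    trait = c("Body Mass Index", "height"),
                    stringsAsFactors = FALSE)
  out <- exclude_by_annotation(rec, ann, "body mass index")
  expect_equal(out$records$snp_id, c("rs2", "rs3"))
  expect_equal(out$report$snp_id, "rs1")
  # empty excluded set is the identity
  expect_equal(exclude_by_annotation(rec, ann, character())$records, rec)
})

test_that("selection composes the stages in order and reports every drop", {
  truth <- simulation_truth(seed = 21, n_snps = 60, ld_block_size = 4,
                            ld_rho = 0.9)
  panel <- simulate_gwas_panel(truth)
  ann <- data.frame(snp_id = panel$exposure$snp_id[1:3],
                    trait = "body mass index", stringsAsFactors = FALSE)
  cfg <- selection_config(excluded_traits = "body mass index")
  sel <- select_instruments(panel$exposure, panel$ld, cfg,
                            annotations = ann, sd_trait = 1)
  expect_equal(sel$stages, c("pvalue", "clump", "f_statistic", "annotation"))
  # exactly one report row per dropped SNP; selected + dropped = input
  dropped <- setdiff(panel$exposure$snp_id, sel$records$snp_id)
  expect_setequal(sel$report$snp_id, dropped)
  expect_equal(anyDuplicated(sel$report$snp_id), 0)
  expect_true(all(sel$records$f_value >= cfg$f_min))
  expect_true(all(sel$records$pvalue < cfg$p_threshold))
})

test_that("selection is idempotent", {
  truth <- simulation_truth(seed = 22, n_snps = 40, ld_block_size = 2,
                            ld_rho = 0.8)
  panel <- simulate_gwas_panel(truth)
  cfg <- selection_config()
  once <- select_instruments(panel$exposure, panel$ld, cfg, sd_trait = 1)
  twice <- select_instruments(once$records, panel$ld, cfg, sd_trait = 1)
  expect_equal(twice$records, once$records)
  expect_equal(nrow(twice$report), 0)
})

test_that("exposures with too few surviving instruments are marked", {
  truth <- simulation_truth(seed = 23, n_snps = 3, gamma_sd = 1e-4)
  panel <- simulate_gwas_panel(truth) # tiny effects: nothing passes p<1e-5
  sel <- select_instruments(panel$exposure, panel$ld, selection_config(),
                            sd_trait = 1)
  expect_equal(sel$status, "too_few_instruments")
})
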