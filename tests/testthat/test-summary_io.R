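well_formed <- function(n = 3) {
  data.frame(snp_id = sprintf("rs%d", seq_len(n)), chrom = "1",
             pos = seq_len(n) * 1000L, effect_allele = "A",
             other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.02,
             pvalue = 1e-6, n_samples = 7824, stringsAsFactors = FALSE)
}

test_that("well-formed tables read back with no rejects", {
  path <- tempfile(fileext = ".tsv")
  write_results_table(well_formed(3), path)
  rec <- suppressMessages(read_summary_stats(path))
  expect_equal(nrow(rec), 3)
  expect_equal(nrow(attr(rec, "rejects")), 0)
})

test_that("invalid rows are rejected with a reason, never coerced", {
  tab <- well_formed(4)
  tab$se[2] <- 0
  tab$other_allele[3] <- "A" # same as effect allele
  out <- validate_summary_stats(tab)
  expect_equal(nrow(out$records), 2)
  expect_setequal(out$rejects$reason,
                  c("non-positive se", "identical alleles"))
  # totality: every row is either valid or rejected
  expect_equal(nrow(out$records) + nrow(out$rejects), nrow(tab))
})

test_that("eaf may be missing but must be in (0,1) when present", {
  tab <- well_formed(3)
  tab$eaf[1] <- NA
  tab$eaf[2] <- 1.2
  out <- validate_summary_stats(tab)
  expect_equal(out$records$snp_id, c("rs1", "rs3"))
  expect_true(is.na(out$records$eaf[1]))
  expect_equal(out$rejects$reason, "eaf outside (0,1)")
})

test_that("duplicate snp_id and bad p-values are rejected", {
  tab <- well_formed(3)
  tab$snp_id[2] <- "rs1"
  tab$pvalue[3] <- 0
  out <- validate_summary_stats(tab)
  expect_equal(nrow(out$records), 1)
  expect_setequal(out$rejects$reason,
                  c("duplicate snp_id", "pvalue outside (0,1]"))
})

test_that("a missing mapped column is a hard error naming the column", {
  path <- tempfile(fileext = ".tsv")
  tab <- well_formed(2)
  names(tab)[names(tab) == "se"] <- "odd_name"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(path), "se")
})

test_that("dialect presets map repository-style headers", {
  tab <- well_formed(2)
  names(tab) <- c("rsids", "#chrom", "pos", "alt", "ref", "af_alt", "beta",
                  "sebeta", "pval", "n")
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- suppressMessages(read_summary_stats(path, finngen_dialect()))
  expect_equal(rec$snp_id, c("rs1", "rs2"))
  expect_equal(rec$effect_allele, c("A", "A"))
})

test_that("write/read round-trips summary statistics field-for-field", {
  tab <- well_formed(5)
  tab$beta <- c(-0.12, 0, 0.007, 1.5, -2)
  tab$eaf <- c(0.011, 0.5, 0.931, 0.25, 0.75)
  path <- tempfile(fileext = ".tsv")
  write_results_table(tab, path)
  back <- suppressMessages(read_summary_stats(path))
  attr(back, "rejects") <- NULL
  expect_equal(back, tab)
})

test_that("writing handles empty input and rejects mixed schemas", {
  path <- tempfile(fileext = ".tsv")
  write_results_table(well_formed(1)[0, ], path)
  expect_equal(length(readLines(path)), 1) # header only
  expect_error(
    write_results_table(list(well_formed(1),
                             data.frame(other = 1)), path),
    "mixed schemas")
})

test_that("ld_matrix enforces symmetry, unit diagonal and [0,1] range", {
  m <- diag(2)
  expect_silent(ld_matrix(c("a", "b"), m))
  bad <- m; bad[1, 2] <- 0.5
  expect_error(ld_matrix(c("a", "b"), bad), "symmetric")
  bad <- m; diag(bad) <- 0.9
  expect_error(ld_matrix(c("a", "b"), bad), "diagonal")
  bad <- m; bad[1, 2] <- bad[2, 1] <- 1.4
  expect_error(ld_matrix(c("a", "b"), bad), "symmetric|\\[0,1\\]")
})

test_that("pathway and annotation tables validate their contracts", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tpathway_name\tmembers",
               "pw1\tvitamin B6\tm1,m2,m3",
               "pw2\tlipids\tm2"), path)
  pw <- read_pathway_table(path)
  expect_equal(pw$members[[1]], c("m1", "m2", "m3"))
  writeLines(c("pathway_id\tpathway_name\tmembers",
               "pw1\ta\tm1", "pw1\tb\tm2"), path)
  expect_error(read_pathway_table(path), "unique")
  writeLines(c("snp_id\ttrait", "rs1\tbody mass index"), path)
  ann <- read_annotation_table(path)
  expect_equal(ann$trait, "body mass index")
})
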