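# Independent oracles and fixture builders used across the suite.

# Step-up Benjamini-Hochberg from the definition:
# adj_(i) = min over j >= i of p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive greedy clumping written independently of clump(): explicit
# re-sorting of the pool each round and a row-by-row window scan.
oracle_clump <- function(records, ld, r2max, kb) {
  keep <- character(0)
  pool <- records
  while (nrow(pool) > 0) {
    ord <- pool[order(pool$pvalue, pool$pos, pool$snp_id), ]
    top <- ord[1, ]
    keep <- c(keep, top$snp_id)
    pool <- ord[-1, , drop = FALSE]
    if (nrow(pool) == 0) break
    drop <- logical(nrow(pool))
    for (i in seq_len(nrow(pool))) {
      if (pool$chrom[i] == top$chrom &&
          abs(pool$pos[i] - top$pos) <= kb * 1000 &&
          ld[top$snp_id, pool$snp_id[i]] > r2max) {
        drop[i] <- TRUE
      }
    }
    pool <- pool[!drop, , drop = FALSE]
  }
  out <- records[records$snp_id %in% keep, ]
  rownames(out) <- NULL
  out
}

# Minimal instrument table for estimator tests.
make_insts <- function(beta_exp, beta_out, se_exp = 0.02, se_out = 0.1,
                       snp_id = sprintf("rs%03d", seq_along(beta_exp))) {
  data.frame(snp_id = snp_id,
             beta_exp = beta_exp, se_exp = rep_len(se_exp, length(beta_exp)),
             beta_out = beta_out, se_out = rep_len(se_out, length(beta_exp)),
             eaf_exp = 0.3, eaf_out = 0.3, f_value = NA_real_,
             stringsAsFactors = FALSE)
}

# Instruments whose per-SNP Wald ratios and first-order ratio se are given.
insts_from_ratios <- function(ratios, ratio_se) {
  make_insts(beta_exp = rep(1, length(ratios)), beta_out = ratios,
             se_exp = 1e-12, se_out = ratio_se)
}

# Random summary-stat panel plus a consistent random LD matrix, for the
# clumping and harmonization property tests.
random_panel <- function(n, seed) {
  set.seed(seed)
  pairs <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  pick <- sample(nrow(pairs), n, replace = TRUE)
  rec <- data.frame(
    snp_id = sprintf("rs%04d", sample.int(9999, n)),
    chrom = sample(c("1", "2"), n, replace = TRUE),
    pos = sample.int(2e6, n),
    effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
    eaf = runif(n, 0.05, 0.95),
    beta = rnorm(n, 0, 0.1), se = runif(n, 0.005, 0.05),
    pvalue = runif(n), n_samples = 7824, stringsAsFactors = FALSE)
  # repeated p-values exercise the position/id tie-break
  dup <- sample.int(n, max(2, n %/% 10))
  rec$pvalue[dup] <- rec$pvalue[dup[1]]
  base <- matrix(rnorm(40 * n), 40, n)
  r2 <- stats::cor(base)^2
  hot <- sample.int(n, max(2, n %/% 5))
  for (i in hot) {
    j <- sample.int(n, 1)
    if (j != i) {
      r2[i, j] <- r2[j, i] <- runif(1, 0.2, 1)
    }
  }
  diag(r2) <- 1
  list(records = rec, ld = ld_matrix(rec$snp_id, r2))
}
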