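#' Ground-truth parameters for a synthetic two-sample GWAS
#'
#' Bundles every parameter of the synthetic generator: the true causal effect
#' of the exposure on the (binary) outcome, the instrument panel size and
#' minor-allele-frequency spectrum, the pleiotropy regime (fraction of invalid
#' instruments and the distribution of their direct outcome effects), the two
#' GWAS sample sizes, and the block LD structure. The defaults emulate the
#' study conditions of a blood-metabolite exposure GWAS (7,824 individuals)
#' against a rare binary outcome cohort (234 cases / 265,626 controls,
#' effective n via [effective_n()]).
#'
#' Per-SNP true exposure effects are drawn as normal(0, `gamma_sd`); when
#' `gamma_sd` is `NULL` it is set so that the median per-SNP F-statistic at
#' `n_exposure` is approximately `target_median_f` (default 30).
#'
#' @param theta True causal effect (log-odds of outcome per unit exposure).
#' @param n_snps Number of candidate instruments (>= 3).
#' @param maf_range Interval for minor-allele frequencies.
#' @param prop_invalid Fraction of SNPs with pleiotropic direct effects, in
#'   \[0,1).
#' @param pleiotropy_mean Mean of direct SNP-to-outcome effects (directional
#'   pleiotropy when nonzero).
#' @param pleiotropy_sd Spread of direct effects.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_outcome Outcome GWAS effective sample size.
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho Within-block adjacent-SNP correlation, in \[0,1).
#' @param gamma_sd SD of true per-SNP exposure effects; `NULL` for automatic.
#' @param target_median_f Median F-statistic targeted by the automatic
#'   `gamma_sd`.
#' @param seed Integer RNG seed; identical truth objects yield byte-identical
#'   synthetic tables.
#' @return A list of class `simulation_truth`.
#' @export
#' @examples
#' truth <- simulation_truth(theta = 0.3, n_snps = 30, seed = 1)
#' panel <- simulate_gwas_panel(truth)
#' str(panel$truth$gamma_sd)
simulation_truth <- function(theta = 0, n_snps = 30,
                             maf_range = c(0.05, 0.5), prop_invalid = 0,
                             pleiotropy_mean = 0, pleiotropy_sd = 0.05,
                             n_exposure = 7824,
                             n_outcome = effective_n(234, 265626),
                             ld_block_size = 1, ld_rho = 0,
                             gamma_sd = NULL, target_median_f = 30,
                             seed = 1) {
  stopifnot(n_snps >= 3, prop_invalid >= 0, prop_invalid < 1,
            n_exposure > 0, n_outcome > 0, ld_block_size >= 1,
            ld_rho >= 0, ld_rho < 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (is.null(gamma_sd)) {
    # median F ~ median over j of gamma_j^2 * 2 p_j (1-p_j) * n_exposure with
    # gamma_j^2 ~ gamma_sd^2 * chisq(1); use the mean maf for the 2p(1-p) term
    mbar <- mean(maf_range)
    gamma_sd <- sqrt(target_median_f /
                       (stats::qchisq(0.5, 1) * 2 * mbar * (1 - mbar) *
                          n_exposure))
  }
  out <- list(theta = theta, n_snps = as.integer(n_snps),
              maf_range = maf_range, prop_invalid = prop_invalid,
              pleiotropy_mean = pleiotropy_mean,
              pleiotropy_sd = pleiotropy_sd,
              n_exposure = n_exposure, n_outcome = n_outcome,
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              gamma_sd = gamma_sd, seed = as.integer(seed))
  class(out) <- "simulation_truth"
  out
}

#' Effective sample size of a case-control GWAS
#'
#' `4 / (1/cases + 1/controls)`: the sample size of a balanced study with the
#' same power, used when emulating imbalanced cohorts (e.g. 234 cases vs
#' 265,626 controls).
#'
#' @param cases,controls Case and control counts.
#' @return Effective sample size.
#' @export
effective_n <- function(cases, controls) 4 / (1 / cases + 1 / controls)

# Deterministic SNP panel (maf, alleles, positions, true effects, invalid set)
# shared by the exposure and outcome generators. LD blocks are placed 1 Mb
# apart (well beyond any clumping window); SNPs within a block sit 1 kb apart.
snp_panel <- function(truth) {
  with_seed(truth$seed, {
    n <- truth$n_snps
    maf <- stats::runif(n, truth$maf_range[1], truth$maf_range[2])
    # effect alleles aligned to the exposure-increasing allele: half-normal
    # magnitudes (same chi-square law as |normal|, so the median-F target
    # holds). Directional pleiotropy is defined in this oriented frame.
    gamma <- abs(stats::rnorm(n, 0, truth$gamma_sd))
    n_invalid <- floor(truth$prop_invalid * n)
    invalid_idx <- if (n_invalid > 0) sort(sample.int(n, n_invalid)) else integer(0)
    alpha <- numeric(n)
    if (n_invalid > 0) {
      alpha[invalid_idx] <- stats::rnorm(n_invalid, truth$pleiotropy_mean,
                                         truth$pleiotropy_sd)
    }
    # non-palindromic allele pairs so synthetic panels harmonize losslessly
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- sample.int(nrow(pairs), n, replace = TRUE)
    block <- (seq_len(n) - 1L) %/% truth$ld_block_size
    within <- (seq_len(n) - 1L) %% truth$ld_block_size
    list(snp_id = sprintf("rs%06d", seq_len(n)),
         chrom = rep("1", n),
         pos = block * 1000000L + within * 1000L + 10000L,
         effect_allele = pairs[pick, 1L], other_allele = pairs[pick, 2L],
         maf = maf, gamma = gamma, alpha = alpha, invalid_idx = invalid_idx)
  })
}

summary_se <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

#' Simulate exposure GWAS summary statistics
#'
#' Observed effects are `gamma_j + noise` with the standardized-trait standard
#' error `1/sqrt(2*eaf*(1-eaf)*n_exposure)`; p-values follow the normal
#' approximation. Deterministic given the truth's seed.
#'
#' @param truth A [simulation_truth()] object.
#' @return data.frame of summary-statistic records (one per SNP).
#' @export
simulate_exposure_stats <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  panel <- snp_panel(truth)
  se <- summary_se(panel$maf, truth$n_exposure)
  beta <- with_seed(truth$seed + 1L,
                    panel$gamma + stats::rnorm(truth$n_snps, 0, se))
  data.frame(snp_id = panel$snp_id, chrom = panel$chrom, pos = panel$pos,
             effect_allele = panel$effect_allele,
             other_allele = panel$other_allele, eaf = panel$maf,
             beta = beta, se = se,
             pvalue = pmax(two_sided_p(beta / se), .Machine$double.xmin),
             n_samples = truth$n_exposure, stringsAsFactors = FALSE)
}

#' Simulate outcome GWAS summary statistics
#'
#' Per-SNP outcome association `theta * gamma_j + alpha_j + noise` on the
#' log-odds scale, where `alpha_j` is zero for valid instruments and drawn
#' from the pleiotropy distribution for the invalid fraction. A distinct
#' `cohort_label` yields an independent noise realization with the same
#' expectations (a replication cohort).
#'
#' @param truth A [simulation_truth()] object.
#' @param exposure_truth_effects The per-SNP true exposure effects (the
#'   `gamma` element of [simulate_gwas_panel()]'s output).
#' @param cohort_label Label identifying the cohort; part of the noise seed.
#' @param n_outcome Effective sample size for this cohort (defaults to the
#'   truth's).
#' @return data.frame of summary-statistic records (one per SNP).
#' @export
simulate_outcome_stats <- function(truth, exposure_truth_effects,
                                   cohort_label = "primary",
                                   n_outcome = truth$n_outcome) {
  stopifnot(inherits(truth, "simulation_truth"))
  panel <- snp_panel(truth)
  if (length(exposure_truth_effects) != truth$n_snps ||
      max(abs(exposure_truth_effects - panel$gamma)) > 1e-12) {
    stop("SNP panel mismatch: exposure effects do not match this truth's panel")
  }
  se <- summary_se(panel$maf, n_outcome)
  mu <- truth$theta * panel$gamma + panel$alpha
  beta <- with_seed(truth$seed + 2L + label_offset(cohort_label),
                    mu + stats::rnorm(truth$n_snps, 0, se))
  data.frame(snp_id = panel$snp_id, chrom = panel$chrom, pos = panel$pos,
             effect_allele = panel$effect_allele,
             other_allele = panel$other_allele, eaf = panel$maf,
             beta = beta, se = se,
             pvalue = pmax(two_sided_p(beta / se), .Machine$double.xmin),
             n_samples = n_outcome, stringsAsFactors = FALSE)
}

#' Simulate block LD structure
#'
#' Builds a block-diagonal r-squared matrix with within-block
#' `r2 = ld_rho^(2|i-j|)` (an AR(1) correlation, squared) and the matching LD
#' scores (row sums of r2, which include the unit self term).
#'
#' @param truth A [simulation_truth()] object.
#' @return list with `r2` (an [ld_matrix()]) and `ld_scores` (data.frame:
#'   snp_id, ld_score).
#' @export
simulate_ld <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  panel <- snp_panel(truth)
  n <- truth$n_snps
  block <- (seq_len(n) - 1L) %/% truth$ld_block_size
  idx <- seq_len(n)
  dist <- abs(outer(idx, idx, "-"))
  same <- outer(block, block, "==")
  r2 <- ifelse(same, truth$ld_rho^(2 * dist), 0)
  diag(r2) <- 1
  m <- ld_matrix(panel$snp_id, r2)
  list(r2 = m,
       ld_scores = data.frame(snp_id = panel$snp_id,
                              ld_score = rowSums(r2),
                              stringsAsFactors = FALSE))
}

#' Simulate a complete two-sample panel with ground truth
#'
#' Convenience wrapper returning the exposure table, one outcome table per
#' cohort label, the LD structure, and the full ground truth (true per-SNP
#' effects, pleiotropic direct effects, invalid-instrument index set, and the
#' truth object itself).
#'
#' @param truth A [simulation_truth()] object.
#' @param cohorts Named numeric vector: cohort label -> effective sample size.
#'   Defaults to a single `primary` cohort at the truth's `n_outcome`.
#' @return list: `exposure`, `outcomes` (named list of data.frames), `ld`,
#'   `ld_scores`, `gamma`, `alpha`, `invalid_idx`, `truth`.
#' @export
simulate_gwas_panel <- function(truth,
                                cohorts = c(primary = truth$n_outcome)) {
  panel <- snp_panel(truth)
  ld <- simulate_ld(truth)
  outcomes <- lapply(seq_along(cohorts), function(i) {
    simulate_outcome_stats(truth, panel$gamma, names(cohorts)[i],
                           n_outcome = cohorts[[i]])
  })
  names(outcomes) <- names(cohorts)
  list(exposure = simulate_exposure_stats(truth), outcomes = outcomes,
       ld = ld$r2, ld_scores = ld$ld_scores, gamma = panel$gamma,
       alpha = panel$alpha, invalid_idx = panel$invalid_idx, truth = truth)
}

#' Simulate a multi-exposure screening panel
#'
#' Generates an independent instrument panel per exposure (as in a metabolite
#' screen, where each metabolite has its own instruments) with a handful of
#' planted causal exposures and two outcome cohorts for replication.
#'
#' @param n_exposures Number of exposures in the panel.
#' @param n_causal Number of planted causal exposures (the first `n_causal`).
#' @param theta_causal True causal effect for the planted exposures.
#' @param cohorts Named numeric vector of cohort effective sample sizes; the
#'   first is the primary analysis, the second the replication.
#' @param seed Integer seed; exposure e uses seed + e.
#' @param ... Further arguments passed to [simulation_truth()] (panel size,
#'   pleiotropy regime, ...).
#' @return list: `panels` (named list of [simulate_gwas_panel()] outputs) and
#'   `truth_table` (data.frame: exposure_id, theta, causal).
#' @export
simulate_screen_panel <- function(n_exposures = 50, n_causal = 3,
                                  theta_causal = 0.5,
                                  cohorts = c(primary = effective_n(234, 265626),
                                              replication = effective_n(99, 456249)),
                                  seed = 1, ...) {
  stopifnot(n_causal <= n_exposures, length(cohorts) >= 1)
  ids <- sprintf("met_%03d", seq_len(n_exposures))
  theta <- c(rep(theta_causal, n_causal), rep(0, n_exposures - n_causal))
  panels <- lapply(seq_len(n_exposures), function(e) {
    truth <- simulation_truth(theta = theta[e], seed = seed + e, ...)
    p <- simulate_gwas_panel(truth, cohorts = cohorts)
    # distinct rsID namespace per exposure
    new_ids <- sprintf("%s_%s", ids[e], p$exposure$snp_id)
    p$exposure$snp_id <- new_ids
    for (k in seq_along(p$outcomes)) p$outcomes[[k]]$snp_id <- new_ids
    dimnames(p$ld) <- list(new_ids, new_ids)
    p$ld_scores$snp_id <- new_ids
    p
  })
  names(panels) <- ids
  list(panels = panels,
       truth_table = data.frame(exposure_id = ids, theta = theta,
                                causal = theta != 0,
                                stringsAsFactors = FALSE))
}

#' Simulate z-score panels for LD score regression
#'
#' Generates per-SNP z-scores for two traits under the LDSC model: the
#' expected chi-square of trait i at SNP j is `1 + n_i * h2_i * l_j / m`, and
#' the cross-trait expectation is `rg * sqrt(h2_1 h2_2 n_1 n_2) * l_j / m`.
#' Shared per-SNP genetic effects with correlation `rg` generate the
#' co-heritability signal.
#'
#' @param ld_scores Numeric vector of per-SNP LD scores (>= 1).
#' @param n1,n2 GWAS sample sizes of the two traits.
#' @param h2_1,h2_2 True SNP heritabilities.
#' @param rg True genetic correlation in \[-1,1\].
#' @param seed Integer seed.
#' @return list with `z1`, `z2` numeric vectors of length `length(ld_scores)`.
#' @export
simulate_ldsc_zscores <- function(ld_scores, n1, n2, h2_1 = 0.3, h2_2 = 0.3,
                                  rg = 0, seed = 1) {
  m <- length(ld_scores)
  with_seed(seed, {
    a1 <- stats::rnorm(m)
    a2 <- rg * a1 + sqrt(1 - rg^2) * stats::rnorm(m)
    s1 <- sqrt(n1 * h2_1 * ld_scores / m)
    s2 <- sqrt(n2 * h2_2 * ld_scores / m)
    list(z1 = s1 * a1 + stats::rnorm(m),
         z2 = s2 * a2 + stats::rnorm(m))
  })
}
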