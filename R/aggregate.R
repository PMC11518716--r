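#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment over one family of exposures
#' (delegates to [stats::p.adjust()] after validating the inputs).
#'
#' @param pvalues Numeric vector, all in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Significance tier of one exposure
#'
#' `significant` when the FDR-adjusted p is below `fdr_threshold`;
#' `suggestive` when only the raw p is below `p_threshold`; otherwise `null`.
#'
#' @param raw_pvalue,fdr_value Raw and BH-adjusted p-values
#'   (`fdr_value >= raw_pvalue`).
#' @param fdr_threshold,p_threshold Tier cutoffs (defaults 0.05).
#' @return Character vector of tiers (vectorized).
#' @export
assign_tier <- function(raw_pvalue, fdr_value, fdr_threshold = 0.05,
                        p_threshold = 0.05) {
  stopifnot(all(fdr_value >= raw_pvalue - 1e-12))
  ifelse(fdr_value < fdr_threshold, "significant",
         ifelse(raw_pvalue < p_threshold, "suggestive", "null"))
}

#' Fixed-effect inverse-variance meta-analysis of two MR results
#'
#' `w_i = 1/se_i^2`, `beta = sum(w_i beta_i)/sum(w_i)`,
#' `se = 1/sqrt(sum(w_i))`, two-sided normal p; both inputs must be on the
#' log-odds scale.
#'
#' @param result_1,result_2 One-row data.frames with `beta` and `se` columns
#'   (e.g. [ivw()] output). A `scale` column, when present on either, must
#'   agree between the two.
#' @return One-row data.frame: beta_combined, se_combined, pvalue, or_value,
#'   ci_low, ci_high.
#' @export
meta_fixed <- function(result_1, result_2) {
  s1 <- if ("scale" %in% names(result_1)) result_1$scale else "log_odds"
  s2 <- if ("scale" %in% names(result_2)) result_2$scale else "log_odds"
  if (!identical(s1, s2)) stop("scale mismatch between meta-analysis inputs")
  w <- c(1 / result_1$se^2, 1 / result_2$se^2)
  b <- c(result_1$beta, result_2$beta)
  beta <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  oc <- or_columns(beta, se)
  data.frame(beta_combined = beta, se_combined = se,
             pvalue = max(two_sided_p(beta / se), .Machine$double.xmin),
             or_value = oc$or_value, ci_low = oc$ci_low,
             ci_high = oc$ci_high)
}

#' Direction consistency of two MR results
#'
#' TRUE iff the two causal estimates share a sign and both are nonzero;
#' exposures failing this are excluded from the candidate set regardless of
#' their meta-analysis p-value.
#'
#' @param result_1,result_2 One-row data.frames with a `beta` column, or bare
#'   numerics.
#' @return Logical.
#' @export
direction_consistency <- function(result_1, result_2) {
  b1 <- if (is.data.frame(result_1)) result_1$beta else result_1
  b2 <- if (is.data.frame(result_2)) result_2$beta else result_2
  b1 != 0 & b2 != 0 & sign(b1) == sign(b2)
}

#' Screen a panel of exposures: FDR, tiers, replication, meta-analysis
#'
#' Applies Benjamini-Hochberg over the primary-analysis (IVW) p-values of all
#' analyzed exposures, assigns tiers, and, for exposures with a replication
#' result, computes direction consistency and the fixed-effect meta-analysis.
#' The final candidate flag is `tier != "null"` AND direction-consistent AND
#' meta p < `meta_alpha`. Exposures without replication keep empty meta fields
#' and the flag is withheld (FALSE).
#'
#' @param primary data.frame with one row per exposure: `exposure_id`,
#'   `n_snp`, `beta`, `se`, `pvalue` (plus any extra columns, carried along).
#' @param replication Optional data.frame with the same columns for the
#'   replication cohort.
#' @param fdr_threshold,p_threshold Tier cutoffs.
#' @param meta_alpha Meta-analysis significance cutoff for the candidate flag.
#' @return data.frame, one row per exposure: the primary columns plus
#'   `or_value`, `ci_low`, `ci_high`, `fdr_value`, `tier`, replication
#'   columns (`rep_*`), `beta_meta`, `se_meta`, `pvalue_meta`, `or_meta`,
#'   `direction_consistent`, `candidate`.
#' @export
screen_panel <- function(primary, replication = NULL, fdr_threshold = 0.05,
                         p_threshold = 0.05, meta_alpha = 0.05) {
  stopifnot(all(c("exposure_id", "beta", "se", "pvalue") %in% names(primary)))
  out <- primary
  oc <- or_columns(out$beta, out$se)
  out$or_value <- oc$or_value
  out$ci_low <- oc$ci_low
  out$ci_high <- oc$ci_high
  out$fdr_value <- bh_fdr(out$pvalue)
  out$tier <- assign_tier(out$pvalue, out$fdr_value, fdr_threshold,
                          p_threshold)
  out$rep_beta <- NA_real_
  out$rep_se <- NA_real_
  out$rep_pvalue <- NA_real_
  out$beta_meta <- NA_real_
  out$se_meta <- NA_real_
  out$pvalue_meta <- NA_real_
  out$or_meta <- NA_real_
  out$ci_low_meta <- NA_real_
  out$ci_high_meta <- NA_real_
  out$direction_consistent <- NA
  if (!is.null(replication) && nrow(replication) > 0L) {
    idx <- match(out$exposure_id, replication$exposure_id)
    for (i in which(!is.na(idx))) {
      r <- replication[idx[i], ]
      out$rep_beta[i] <- r$beta
      out$rep_se[i] <- r$se
      out$rep_pvalue[i] <- r$pvalue
      m <- meta_fixed(out[i, c("beta", "se")], r[, c("beta", "se")])
      out$beta_meta[i] <- m$beta_combined
      out$se_meta[i] <- m$se_combined
      out$pvalue_meta[i] <- m$pvalue
      out$or_meta[i] <- m$or_value
      out$ci_low_meta[i] <- m$ci_low
      out$ci_high_meta[i] <- m$ci_high
      out$direction_consistent[i] <- direction_consistency(out$beta[i],
                                                           r$beta)
    }
  }
  out$candidate <- out$tier != "null" &
    !is.na(out$direction_consistent) & out$direction_consistent &
    !is.na(out$pvalue_meta) & out$pvalue_meta < meta_alpha
  out
}
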