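#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (ratio_j - beta_IVW)^2` with first-order inverse-variance
#' weights, referred to a chi-square with n-1 degrees of freedom (upper tail).
#'
#' @param insts Instrument data.frame with >= 2 rows.
#' @return list: `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(insts) {
  n <- nrow(insts)
  if (n < 2L) stop("Cochran's Q needs >= 2 instruments")
  r <- ratio_estimates(insts)
  w <- 1 / r$se^2
  beta <- sum(w * r$b) / sum(w)
  q <- sum(w * (r$b - beta)^2)
  list(q_stat = q, q_df = n - 1L,
       q_pvalue = max(stats::pchisq(q, n - 1, lower.tail = FALSE),
                      .Machine$double.xmin))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept block of the MR-Egger regression with a two-sided t-test on
#' n-2 degrees of freedom; a nonzero intercept indicates directional
#' pleiotropy.
#'
#' @param insts Instrument data.frame with >= 3 rows.
#' @return list: `intercept`, `se`, `pvalue`.
#' @export
egger_intercept_test <- function(insts) {
  fit <- mr_egger(insts)
  list(intercept = fit$intercept$value, se = fit$intercept$se,
       pvalue = fit$intercept$pvalue)
}

# Vectorized leave-one-out origin-WLS slopes: theta_{-j} for all j.
# IVW on first-order ratios == WLS of by on bx through the origin with
# weights 1/se_out^2.
loo_slopes <- function(bx, by, w) {
  num <- sum(w * bx * by)
  den <- sum(w * bx^2)
  (num - w * bx * by) / (den - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Detects horizontal pleiotropy through the heterogeneity of leave-one-out
#' residuals. The observed statistic is the weighted residual sum of squares
#' `RSS = sum_j w_j (beta_out_j - theta_{-j} beta_exp_j)^2` with
#' `w_j = 1/se_out_j^2` and `theta_{-j}` the IVW estimate excluding SNP j. Its
#' null distribution is simulated parametrically: per draw, exposure effects
#' from `normal(beta_exp_j, se_exp_j)` and outcome effects from
#' `normal(theta_{-j} * drawn exposure effect, se_out_j)`; the global p-value
#' is the empirical upper tail (floored at `1/(n_sim+1)`). The outlier test
#' compares each SNP's observed residual contribution with its simulated
#' distribution, Bonferroni-corrected at `outlier_alpha`. The distortion test
#' compares the outlier-free estimate against estimates from `n_sim` random
#' removals of the same size. The corrected estimate is IVW on the
#' outlier-free set.
#'
#' @param insts Instrument data.frame with >= 4 rows.
#' @param n_sim Simulated null draws (also random removals for distortion).
#' @param outlier_alpha Significance level for the Bonferroni outlier test.
#' @param seed Integer seed; all stochastic steps are reproducible.
#' @param ivw_mode Mode for the corrected IVW estimate.
#' @return list: `global_rss`, `global_pvalue`, `outlier_ids`,
#'   `outlier_pvalues` (named, Bonferroni-adjusted), `distortion_pvalue` (NA
#'   when no outliers), `corrected` (one-row MR-result data.frame or NULL).
#' @export
mr_presso <- function(insts, n_sim = 1000, outlier_alpha = 0.05, seed = 1,
                      ivw_mode = "random") {
  n <- nrow(insts)
  if (n < 4L) stop("MR-PRESSO needs >= 4 instruments")
  bx <- insts$beta_exp
  by <- insts$beta_out
  w <- 1 / insts$se_out^2
  theta_loo <- loo_slopes(bx, by, w)
  contrib_obs <- w * (by - theta_loo * bx)^2
  rss_obs <- sum(contrib_obs)

  sims <- with_seed(seed, {
    bx_s <- matrix(stats::rnorm(n_sim * n, rep(bx, each = n_sim),
                                rep(insts$se_exp, each = n_sim)), n_sim, n)
    by_s <- matrix(stats::rnorm(n_sim * n,
                                bx_s * rep(theta_loo, each = n_sim),
                                rep(insts$se_out, each = n_sim)), n_sim, n)
    list(bx = bx_s, by = by_s)
  })
  w_mat <- matrix(w, n_sim, n, byrow = TRUE)
  num <- rowSums(w_mat * sims$bx * sims$by)
  den <- rowSums(w_mat * sims$bx^2)
  theta_loo_s <- (num - w_mat * sims$bx * sims$by) /
    (den - w_mat * sims$bx^2)
  contrib_s <- w_mat * (sims$by - theta_loo_s * sims$bx)^2
  rss_s <- rowSums(contrib_s)

  global_p <- (1 + sum(rss_s >= rss_obs)) / (n_sim + 1)
  outlier_raw <- (1 + colSums(contrib_s >=
                                matrix(contrib_obs, n_sim, n, byrow = TRUE))) /
    (n_sim + 1)
  outlier_adj <- pmin(outlier_raw * n, 1)
  names(outlier_adj) <- insts$snp_id
  outliers <- insts$snp_id[outlier_adj < outlier_alpha]

  distortion_p <- NA_real_
  corrected <- NULL
  n_out <- length(outliers)
  if (n_out > 0L && n - n_out >= 2L) {
    keep <- !(insts$snp_id %in% outliers)
    corrected <- ivw(insts[keep, ], mode = ivw_mode)
    theta_all <- ivw(insts, mode = ivw_mode)$beta
    d_obs <- corrected$beta - theta_all
    d_rand <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(n, n_out)
        sub <- insts[-drop_idx, , drop = FALSE]
        ivw(sub, mode = ivw_mode)$beta - theta_all
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (n_sim + 1)
  }
  list(global_rss = rss_obs, global_pvalue = global_p,
       outlier_ids = outliers, outlier_pvalues = outlier_adj,
       distortion_pvalue = distortion_p, corrected = corrected)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the IVW causal effect with each instrument removed in turn;
#' row order matches the instrument order.
#'
#' @param insts Instrument data.frame with >= 3 rows.
#' @param ivw_mode IVW mode for the reduced fits.
#' @return data.frame: snp_id (the excluded SNP), beta, se, pvalue.
#' @export
leave_one_out <- function(insts, ivw_mode = "random") {
  n <- nrow(insts)
  if (n < 3L) stop("leave-one-out needs >= 3 instruments")
  rows <- lapply(seq_len(n), function(j) {
    fit <- ivw(insts[-j, , drop = FALSE], mode = ivw_mode)
    data.frame(snp_id = insts$snp_id[j], beta = fit$beta, se = fit$se,
               pvalue = fit$pvalue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full sensitivity report for one instrument set
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, MR-PRESSO, and
#' leave-one-out into one report. Components whose minimum instrument count is
#' not met are returned as NULL with a logged reason.
#'
#' @param insts Instrument data.frame.
#' @param n_sim,outlier_alpha,seed Passed to [mr_presso()].
#' @param q_alpha Reporting threshold for the heterogeneity flag.
#' @return list of class `sensitivity_report`: `q` (with
#'   `heterogeneity_flag`), `egger`, `presso`, `loo`, `skipped`.
#' @export
sensitivity_report <- function(insts, n_sim = 1000, outlier_alpha = 0.05,
                               seed = 1, q_alpha = 0.05) {
  n <- nrow(insts)
  skipped <- character(0)
  q <- NULL
  egger <- NULL
  presso <- NULL
  loo <- NULL
  if (n >= 2L) {
    q <- cochran_q(insts)
    q$heterogeneity_flag <- q$q_pvalue < q_alpha
  } else skipped <- c(skipped, "cochran_q")
  if (n >= 3L) egger <- egger_intercept_test(insts)
  else skipped <- c(skipped, "egger_intercept")
  if (n >= 4L) {
    presso <- mr_presso(insts, n_sim = n_sim, outlier_alpha = outlier_alpha,
                        seed = seed)
  } else skipped <- c(skipped, "mr_presso")
  if (n >= 3L) loo <- leave_one_out(insts)
  else skipped <- c(skipped, "leave_one_out")
  structure(list(q = q, egger = egger, presso = presso, loo = loo,
                 skipped = skipped),
            class = "sensitivity_report")
}
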