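# One row of causal-estimate output shared by every estimator.
mr_result <- function(method, beta, se, n_snp, pvalue = two_sided_p(beta / se)) {
  oc <- or_columns(beta, se)
  data.frame(method = method, n_snp = as.integer(n_snp), beta = beta, se = se,
             pvalue = max(min(pvalue, 1), .Machine$double.xmin),
             or_value = oc$or_value, ci_low = oc$ci_low, ci_high = oc$ci_high,
             stringsAsFactors = FALSE)
}

# Per-SNP Wald ratios with first-order delta-method standard errors.
ratio_estimates <- function(insts, second_order = FALSE) {
  if (any(insts$beta_exp == 0)) stop("beta_exp = 0: Wald ratio undefined")
  b <- insts$beta_out / insts$beta_exp
  v <- insts$se_out^2 / insts$beta_exp^2
  if (second_order) {
    v <- v + insts$beta_out^2 * insts$se_exp^2 / insts$beta_exp^4
  }
  list(b = b, se = sqrt(v))
}

#' Wald ratio estimate from a single instrument
#'
#' `beta_out / beta_exp`, with the delta-method standard error
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)` (the
#' second-order term is included here since a single SNP offers no pooling to
#' absorb exposure noise; set `second_order = FALSE` for the first-order se).
#'
#' @param inst One-row instrument data.frame (see [harmonize()]).
#' @param second_order Include the exposure-uncertainty term in the se.
#' @return One-row MR-result data.frame.
#' @export
wald_ratio <- function(inst, second_order = TRUE) {
  stopifnot(nrow(inst) == 1L)
  if (inst$beta_exp == 0) stop("beta_exp = 0: Wald ratio undefined")
  r <- ratio_estimates(inst, second_order = second_order)
  mr_result("wald_ratio", r$b, r$se, 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools per-SNP Wald ratios with first-order inverse-variance weights
#' `w_j = 1/se_j^2`; equivalent to weighted least squares of `beta_out` on
#' `beta_exp` through the origin with weights `1/se_out^2`. `mode = "random"`
#' (the default, the pipeline's primary estimator) inflates the fixed-effect
#' standard error by `sqrt(max(1, Q/(n-1)))` (multiplicative random effects);
#' `mode = "fixed"` does not.
#'
#' @param insts Instrument data.frame with >= 2 rows.
#' @param mode `"random"` or `"fixed"`.
#' @return One-row MR-result data.frame (method `ivw_random` / `ivw_fixed`).
#' @export
ivw <- function(insts, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  if (nrow(insts) < 2L) {
    stop("IVW needs >= 2 instruments; use wald_ratio() for a single SNP")
  }
  r <- ratio_estimates(insts)
  w <- 1 / r$se^2
  beta <- sum(w * r$b) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (mode == "random") {
    q <- sum(w * (r$b - beta)^2)
    se <- se * sqrt(max(1, q / (nrow(insts) - 1)))
  }
  mr_result(paste0("ivw_", mode), beta, se, nrow(insts))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept (weights `1/se_out^2`), after orienting all instruments to
#' non-negative exposure effects. The slope estimates the causal effect under
#' the InSIDE assumption; the intercept estimates directional pleiotropy.
#' Standard errors use the estimated residual dispersion, not allowing
#' underdispersion below 1 (multiplicative random effects); p-values are
#' two-sided t with n-2 degrees of freedom.
#'
#' @param insts Instrument data.frame with >= 3 rows.
#' @return list: `result` (one-row MR-result data.frame, method `mr_egger`)
#'   and `intercept` (list: value, se, pvalue).
#' @export
mr_egger <- function(insts) {
  n <- nrow(insts)
  if (n < 3L) stop("MR-Egger needs >= 3 instruments")
  sgn <- ifelse(insts$beta_exp < 0, -1, 1)
  bx <- insts$beta_exp * sgn
  by <- insts$beta_out * sgn
  w <- 1 / insts$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  est <- stats::coef(fit)
  # unit-dispersion covariance, then multiplicative dispersion floored at 1
  x_mat <- cbind(1, bx)
  se_unit <- sqrt(diag(solve(crossprod(x_mat * sqrt(w)))))
  sigma <- sqrt(sum(w * stats::resid(fit)^2) / (n - 2))
  disp <- max(sigma, 1)
  slope <- est[["bx"]]
  slope_se <- unname(se_unit[2]) * disp
  int <- est[["(Intercept)"]]
  int_se <- unname(se_unit[1]) * disp
  p_slope <- 2 * stats::pt(-abs(slope / slope_se), df = n - 2)
  p_int <- 2 * stats::pt(-abs(int / int_se), df = n - 2)
  list(result = mr_result("mr_egger", slope, slope_se, n, pvalue = p_slope),
       intercept = list(value = int, se = int_se,
                        pvalue = max(p_int, .Machine$double.xmin)))
}

# Weighted median of values b with weights w: linear interpolation across
# cumulative-weight midpoints.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - 0.5 * w
  if (p[1] >= 0.5) return(b[1])
  if (p[length(p)] <= 0.5) return(b[length(b)])
  j <- max(which(p < 0.5))
  b[j] + (b[j + 1] - b[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

#' Weighted-median causal estimate
#'
#' The weighted 50th percentile of the per-SNP Wald ratios with normalized
#' inverse-variance weights; consistent when at least half the weight comes
#' from valid instruments. The standard error is a seeded parametric
#' bootstrap: each ratio is resampled from normal(ratio_j, se_j).
#'
#' @param insts Instrument data.frame with >= 3 rows.
#' @param n_boot Bootstrap draws for the standard error.
#' @param seed Integer seed for the bootstrap.
#' @return One-row MR-result data.frame (method `weighted_median`).
#' @export
weighted_median <- function(insts, n_boot = 1000, seed = 1) {
  if (nrow(insts) < 3L) stop("weighted median needs >= 3 instruments")
  r <- ratio_estimates(insts)
  w <- 1 / r$se^2
  beta <- weighted_median_point(r$b, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      weighted_median_point(stats::rnorm(length(r$b), r$b, r$se), w)
    }, numeric(1))
  })
  mr_result("weighted_median", beta, stats::sd(boots), nrow(insts))
}

# Kernel-density mode of ratios with weights; bandwidth = phi x modified
# Silverman rule. mad() can collapse to zero on clustered ratios, so fall back
# to sd, then to the (degenerate) unique value.
kde_mode <- function(b, w, phi = 1) {
  if (stats::sd(b) == 0) return(b[1])
  s <- 0.9 * min(stats::sd(b), stats::mad(b)) * length(b)^(-1 / 5)
  if (s <= 0) s <- 0.9 * stats::sd(b) * length(b)^(-1 / 5)
  d <- suppressWarnings(
    stats::density(b, weights = w / sum(w), bw = phi * s, n = 2048))
  d$x[which.max(d$y)]
}

#' Mode-based causal estimates (simple and weighted)
#'
#' The mode of the kernel-smoothed distribution of per-SNP Wald ratios:
#' unweighted for the simple mode, inverse-variance weighted for the weighted
#' mode. Normal kernel with bandwidth `phi` times a modified Silverman rule on
#' the ratios; standard error by seeded parametric bootstrap.
#'
#' @param insts Instrument data.frame with >= 3 rows.
#' @param variant `"weighted"` or `"simple"`.
#' @param phi Bandwidth multiplier.
#' @param n_boot Bootstrap draws for the standard error.
#' @param seed Integer seed for the bootstrap.
#' @return One-row MR-result data.frame (method `weighted_mode` /
#'   `simple_mode`).
#' @export
mode_estimator <- function(insts, variant = c("weighted", "simple"), phi = 1,
                           n_boot = 1000, seed = 1) {
  variant <- match.arg(variant)
  if (nrow(insts) < 3L) stop("mode estimators need >= 3 instruments")
  r <- ratio_estimates(insts)
  w <- if (variant == "weighted") 1 / r$se^2 else rep(1, length(r$b))
  beta <- kde_mode(r$b, w, phi)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      kde_mode(stats::rnorm(length(r$b), r$b, r$se), w, phi)
    }, numeric(1))
  })
  mr_result(paste0(variant, "_mode"), beta, stats::sd(boots), nrow(insts))
}

#' Run the full estimator suite on one instrument set
#'
#' Runs random-effects IVW (the primary estimator) plus MR-Egger, weighted
#' median, and the simple and weighted modes. With a single instrument only
#' the Wald ratio is returned; methods whose minimum instrument count is not
#' met are skipped with a logged reason (attribute `skipped`).
#'
#' @param insts Instrument data.frame.
#' @param seed Integer seed driving every bootstrap.
#' @param n_boot Bootstrap draws for median/mode standard errors.
#' @param ivw_mode `"random"` (default) or `"fixed"` for the primary IVW.
#' @return MR-result data.frame, one row per method, with attributes
#'   `primary` (the primary method name) and `skipped` (data.frame: method,
#'   reason).
#' @export
run_all_methods <- function(insts, seed = 1, n_boot = 1000,
                            ivw_mode = "random") {
  n <- nrow(insts)
  if (n < 1L) stop("no instruments")
  skipped <- data.frame(method = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (n == 1L) {
    out <- wald_ratio(insts)
    skipped <- data.frame(
      method = c("ivw", "mr_egger", "weighted_median", "simple_mode",
                 "weighted_mode"),
      reason = "fewer instruments than the method requires",
      stringsAsFactors = FALSE)
    attr(out, "primary") <- "wald_ratio"
    attr(out, "skipped") <- skipped
    return(out)
  }
  rows <- list(ivw(insts, mode = ivw_mode))
  if (n >= 3L) {
    rows <- c(rows, list(mr_egger(insts)$result,
                         weighted_median(insts, n_boot = n_boot, seed = seed),
                         mode_estimator(insts, "simple", n_boot = n_boot,
                                        seed = seed + 1L),
                         mode_estimator(insts, "weighted", n_boot = n_boot,
                                        seed = seed + 2L)))
  } else {
    skipped <- data.frame(
      method = c("mr_egger", "weighted_median", "simple_mode",
                 "weighted_mode"),
      reason = "fewer instruments than the method requires",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "primary") <- paste0("ivw_", ivw_mode)
  attr(out, "skipped") <- skipped
  out
}
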