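flip_allele <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every SNP present in both tables to the
#' exposure's effect allele. If the outcome alleles are swapped relative to
#' the exposure, the outcome beta is negated and its eaf replaced by 1 - eaf;
#' if they are the strand complement, they are complemented first and the swap
#' rule then applied. Palindromic SNPs (A/T or C/G) cannot be resolved from
#' allele labels: they are kept only when both allele frequencies lie outside
#' `0.5 +/- palindromic_eaf_window` and imply the same allele orientation,
#' otherwise dropped. Irreconcilable allele pairs are dropped with reason
#' "allele mismatch". Every action is logged per SNP.
#'
#' @param exposure,outcome Validated summary-statistic data.frames. An
#'   `f_value` column on the exposure side (from [select_instruments()]) is
#'   carried through.
#' @param palindromic_eaf_window Half-width of the ambiguous eaf zone around
#'   0.5 (default 0.08: drop when either eaf is in \[0.42, 0.58\]).
#' @return list: `instruments` (data.frame: snp_id, beta_exp, se_exp,
#'   beta_out, se_out, eaf_exp, eaf_out, f_value) and `log` (data.frame:
#'   snp_id, action, reason).
#' @export
#' @examples
#' truth <- simulation_truth(theta = 0.2, seed = 3)
#' panel <- simulate_gwas_panel(truth)
#' h <- harmonize(panel$exposure, panel$outcomes$primary)
#' head(h$instruments)
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]

  n <- length(shared)
  action <- character(n)
  reason <- rep(NA_character_, n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  ea <- ou$effect_allele
  oa <- ou$other_allele

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  # strand complement (non-palindromic only; for palindromic pairs the
  # complement is indistinguishable from a swap and is handled by eaf below)
  comp <- !pal & flip_allele(ea) == ex$effect_allele &
    flip_allele(oa) == ex$other_allele
  comp_swap <- !pal & flip_allele(ea) == ex$other_allele &
    flip_allele(oa) == ex$effect_allele
  ea[comp | comp_swap] <- flip_allele(ea[comp | comp_swap])
  oa[comp | comp_swap] <- flip_allele(oa[comp | comp_swap])

  same <- ea == ex$effect_allele & oa == ex$other_allele
  swap <- ea == ex$other_allele & oa == ex$effect_allele

  beta_out[swap] <- -beta_out[swap]
  eaf_out[swap] <- 1 - eaf_out[swap]

  action[same & !comp] <- "keep"
  action[swap & !comp_swap] <- "flip"
  action[comp] <- "complement"
  action[comp_swap] <- "complement+flip"
  mismatch <- !same & !swap
  action[mismatch] <- "drop"
  reason[mismatch] <- "allele mismatch"

  # palindromic resolution by allele frequency
  lo <- 0.5 - palindromic_eaf_window
  hi <- 0.5 + palindromic_eaf_window
  amb <- pal & !mismatch &
    (is.na(ex$eaf) | is.na(eaf_out) |
       (ex$eaf >= lo & ex$eaf <= hi) | (eaf_out >= lo & eaf_out <= hi) |
       sign(ex$eaf - 0.5) != sign(eaf_out - 0.5))
  action[amb] <- "drop"
  reason[amb] <- "palindromic ambiguous"

  keep <- action != "drop"
  f_val <- if ("f_value" %in% names(ex)) ex$f_value else
    rep(NA_real_, length(shared))
  instruments <- data.frame(
    snp_id = shared[keep],
    beta_exp = ex$beta[keep], se_exp = ex$se[keep],
    beta_out = beta_out[keep], se_out = ou$se[keep],
    eaf_exp = ex$eaf[keep], eaf_out = eaf_out[keep],
    f_value = f_val[keep],
    stringsAsFactors = FALSE)
  rownames(instruments) <- NULL
  list(instruments = instruments,
       log = data.frame(snp_id = shared, action = action, reason = reason,
                        stringsAsFactors = FALSE))
}
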