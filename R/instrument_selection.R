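#' Instrument-selection configuration
#'
#' Defaults follow the screening recipe used for metabolite panels: exposure
#' association p < 1e-5, greedy LD clumping at r2 = 0.01 within 100 kb,
#' per-SNP F-statistic >= 10, and at least 3 instruments per exposure.
#'
#' @param p_threshold Exposure association p-value cutoff.
#' @param clump_r2 Maximum pairwise r-squared retained within the window.
#' @param clump_kb Clumping window in kilobases.
#' @param f_min Minimum per-SNP F-statistic.
#' @param min_snps Minimum instruments per exposure; exposures below this are
#'   marked excluded from analysis.
#' @param excluded_traits Character vector of confounder phenotype labels
#'   (case-insensitive exact match) whose annotated SNPs are removed.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 1e-5, clump_r2 = 0.01,
                             clump_kb = 100, f_min = 10, min_snps = 3,
                             excluded_traits = character()) {
  stopifnot(p_threshold > 0, p_threshold < 1, clump_r2 >= 0, clump_r2 <= 1,
            clump_kb > 0, f_min >= 0, min_snps >= 1)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min,
                 min_snps = as.integer(min_snps),
                 excluded_traits = as.character(excluded_traits)),
            class = "selection_config")
}

#' Filter records by exposure association p-value
#'
#' @param records Summary-statistic data.frame.
#' @param p_threshold Keep records with `pvalue < p_threshold`.
#' @return The qualifying subset, input order preserved.
#' @export
filter_by_pvalue <- function(records, p_threshold) {
  out <- records[records$pvalue < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining record with the smallest p-value (ties:
#' smaller position, then lexicographic snp_id) and removes all remaining
#' records on the same chromosome within `clump_kb` kilobases whose r-squared
#' with it exceeds `clump_r2`. Every retained pair within the window therefore
#' has r2 <= clump_r2.
#'
#' @param records Summary-statistic data.frame.
#' @param ld An [ld_matrix()] covering all records.
#' @param clump_r2 Maximum retained pairwise r-squared.
#' @param clump_kb Window in kilobases (`|delta pos| <= clump_kb * 1000`).
#' @return The retained subset in input order, with attribute `removed`
#'   (data.frame: snp_id, index_snp).
#' @export
clump <- function(records, ld, clump_r2 = 0.01, clump_kb = 100) {
  if (nrow(records) == 0L) return(records)
  absent <- setdiff(records$snp_id, rownames(ld))
  if (length(absent) > 0L) {
    stop("SNP(s) absent from LD matrix: ", paste(absent, collapse = ", "))
  }
  window <- clump_kb * 1000
  remaining <- seq_len(nrow(records))
  kept <- integer(0)
  removed <- data.frame(snp_id = character(0), index_snp = character(0),
                        stringsAsFactors = FALSE)
  while (length(remaining) > 0L) {
    sub <- records[remaining, ]
    o <- order(sub$pvalue, sub$pos, sub$snp_id)[1L]
    idx <- remaining[o]
    kept <- c(kept, idx)
    remaining <- remaining[-o]
    if (length(remaining) == 0L) break
    sub <- records[remaining, ]
    r2 <- ld[records$snp_id[idx], sub$snp_id]
    hit <- sub$chrom == records$chrom[idx] &
      abs(sub$pos - records$pos[idx]) <= window &
      r2 > clump_r2
    if (any(hit)) {
      removed <- rbind(removed,
                       data.frame(snp_id = sub$snp_id[hit],
                                  index_snp = records$snp_id[idx],
                                  stringsAsFactors = FALSE))
      remaining <- remaining[!hit]
    }
  }
  out <- records[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Per-SNP instrument strength (variance explained and F-statistic)
#'
#' Variance explained uses `R2 = 2 * MAF * (1-MAF) * beta_std^2` with
#' `MAF = min(eaf, 1-eaf)`. When the exposure trait SD is supplied,
#' `beta_std = beta / sd_trait`; otherwise the z-score approximation
#' `R2 = F0 / (F0 + N - 2)` with `F0 = (beta/se)^2` is used (logged once per
#' call). The F-statistic is `R2 * (N - 1 - K) / ((1 - R2) * K)` with K = 1 by
#' default (per-SNP F).
#'
#' @param records Summary-statistic data.frame (vectorized over rows).
#' @param n_samples Exposure GWAS sample size (defaults to the records' own).
#' @param k_instruments K in the F formula; 1 for per-SNP strength.
#' @param sd_trait Exposure trait SD placing beta on the standardized scale,
#'   or `NULL` for the z-score approximation.
#' @return data.frame with columns `r_squared`, `f_value`, one row per record.
#' @export
f_statistic <- function(records, n_samples = records$n_samples,
                        k_instruments = 1, sd_trait = NULL) {
  if (any(is.na(records$eaf))) {
    stop("missing eaf: F-statistic requires an effect-allele frequency for ",
         paste(records$snp_id[is.na(records$eaf)], collapse = ", "))
  }
  if (any(n_samples <= k_instruments + 1)) {
    stop("n_samples must exceed k_instruments + 1")
  }
  maf <- pmin(records$eaf, 1 - records$eaf)
  if (!is.null(sd_trait)) {
    beta_std <- records$beta / sd_trait
    r2 <- 2 * maf * (1 - maf) * beta_std^2
  } else {
    message("f_statistic: no trait SD supplied; using the z-score ",
            "approximation R2 = F0/(F0 + N - 2)")
    f0 <- (records$beta / records$se)^2
    r2 <- f0 / (f0 + n_samples - 2)
  }
  if (any(r2 >= 1)) {
    stop("R-squared >= 1 for ", paste(records$snp_id[r2 >= 1], collapse = ", "),
         "; malformed input")
  }
  f <- r2 * (n_samples - 1 - k_instruments) / ((1 - r2) * k_instruments)
  data.frame(r_squared = r2, f_value = f)
}

#' Exclude instruments annotated to confounder traits
#'
#' Removes records whose snp_id carries any annotation whose trait label
#' matches (case-insensitive exact match) an excluded trait. Unannotated SNPs
#' always pass.
#'
#' @param records Summary-statistic data.frame.
#' @param annotations data.frame with columns snp_id, trait (or `NULL`).
#' @param excluded_traits Character vector of confounder labels.
#' @return list: `records` (kept subset) and `report` (data.frame: snp_id,
#'   trait for each removal).
#' @export
exclude_by_annotation <- function(records, annotations, excluded_traits) {
  report <- data.frame(snp_id = character(0), trait = character(0),
                       stringsAsFactors = FALSE)
  if (is.null(annotations) || length(excluded_traits) == 0L ||
      nrow(records) == 0L) {
    return(list(records = records, report = report))
  }
  bad <- annotations[tolower(annotations$trait) %in%
                       tolower(excluded_traits), , drop = FALSE]
  hit <- records$snp_id %in% bad$snp_id
  if (any(hit)) {
    report <- unique(bad[bad$snp_id %in% records$snp_id,
                         c("snp_id", "trait")])
    rownames(report) <- NULL
  }
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = report)
}

#' Select qualified instruments for one exposure
#'
#' Applies, in order: association threshold, greedy LD clumping, F-statistic
#' weak-instrument filter, annotation-based confounder exclusion. Exposures
#' ending with fewer than `min_snps` instruments are marked excluded from
#' analysis. Every dropped SNP appears exactly once in the exclusion report
#' with its first failing stage.
#'
#' @param records Summary-statistic data.frame for one exposure.
#' @param ld An [ld_matrix()] covering the records.
#' @param config A [selection_config()].
#' @param annotations Optional SNP-trait annotation data.frame.
#' @param sd_trait Optional exposure trait SD for [f_statistic()].
#' @return list of class `instrument_selection`: `status` ("ok" or
#'   "too_few_instruments"), `records` (selected, with `f_value` and
#'   `r_squared` columns), `report` (snp_id, stage, reason), `stages`
#'   (character vector recording the applied stage order).
#' @export
select_instruments <- function(records, ld, config = selection_config(),
                               annotations = NULL, sd_trait = NULL) {
  stopifnot(inherits(config, "selection_config"))
  report <- data.frame(snp_id = character(0), stage = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  note <- function(ids, stage, reason) {
    if (length(ids) > 0L) {
      report <<- rbind(report, data.frame(snp_id = ids, stage = stage,
                                          reason = reason,
                                          stringsAsFactors = FALSE))
    }
  }

  kept <- filter_by_pvalue(records, config$p_threshold)
  note(setdiff(records$snp_id, kept$snp_id), "pvalue",
       sprintf("p >= %g", config$p_threshold))

  clumped <- clump(kept, ld, config$clump_r2, config$clump_kb)
  note(setdiff(kept$snp_id, clumped$snp_id), "clump",
       sprintf("r2 > %g within %g kb of a better hit", config$clump_r2,
               config$clump_kb))
  attr(clumped, "removed") <- NULL
  kept <- clumped

  if (nrow(kept) > 0L) {
    fs <- f_statistic(kept, sd_trait = sd_trait)
    kept$r_squared <- fs$r_squared
    kept$f_value <- fs$f_value
    weak <- kept$f_value < config$f_min
    note(kept$snp_id[weak], "f_statistic", sprintf("F < %g", config$f_min))
    kept <- kept[!weak, , drop = FALSE]
  } else {
    kept$r_squared <- numeric(0)
    kept$f_value <- numeric(0)
  }

  ex <- exclude_by_annotation(kept, annotations, config$excluded_traits)
  if (nrow(ex$report) > 0L) {
    note(ex$report$snp_id, "annotation",
         sprintf("annotated to excluded trait '%s'", ex$report$trait))
  }
  kept <- ex$records
  rownames(kept) <- NULL

  status <- if (nrow(kept) < config$min_snps) "too_few_instruments" else "ok"
  structure(list(status = status, records = kept, report = report,
                 stages = c("pvalue", "clump", "f_statistic", "annotation")),
            class = "instrument_selection")
}
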