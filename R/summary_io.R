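#' Column-name dialects for GWAS summary-statistic tables
#'
#' A dialect maps the canonical column names used throughout mrscreen to the
#' column names found in a source file. Presets are provided for FinnGen-style
#' and GWAS-Catalog-style headers; `gwas_dialect()` with no arguments is the
#' package's native header.
#'
#' @param snp_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pvalue,n_samples
#'   Column name in the source file holding the corresponding canonical field.
#' @return A named character vector (canonical name -> source column name).
#' @export
#' @examples
#' gwas_dialect()
#' finngen_dialect()
gwas_dialect <- function(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                         effect_allele = "effect_allele",
                         other_allele = "other_allele", eaf = "eaf",
                         beta = "beta", se = "se", pvalue = "pvalue",
                         n_samples = "n_samples") {
  c(snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n_samples = n_samples)
}

#' @rdname gwas_dialect
#' @export
finngen_dialect <- function() {
  gwas_dialect(snp_id = "rsids", chrom = "#chrom", pos = "pos",
               effect_allele = "alt", other_allele = "ref", eaf = "af_alt",
               beta = "beta", se = "sebeta", pvalue = "pval",
               n_samples = "n")
}

#' @rdname gwas_dialect
#' @export
gwas_catalog_dialect <- function() {
  gwas_dialect(snp_id = "variant_id", chrom = "chromosome",
               pos = "base_pair_location", effect_allele = "effect_allele",
               other_allele = "other_allele",
               eaf = "effect_allele_frequency", beta = "beta",
               se = "standard_error", pvalue = "p_value",
               n_samples = "n")
}

canonical_stat_cols <- c("snp_id", "chrom", "pos", "effect_allele",
                         "other_allele", "eaf", "beta", "se", "pvalue",
                         "n_samples")

valid_bases <- c("A", "C", "G", "T")

#' Validate a GWAS summary-statistic table
#'
#' Splits a table with canonical columns into valid records and rejected rows.
#' Every input row lands in exactly one of the two outputs; rejection reasons
#' name the first violated invariant. A missing (NA) effect-allele frequency is
#' permitted (the record is flagged, not rejected) but such records cannot be
#' used for F-statistics or palindromic resolution downstream.
#'
#' @param x data.frame with the canonical columns (see [gwas_dialect()]).
#' @return list with `records` (valid rows, original order), `rejects`
#'   (data.frame: row, snp_id, reason).
#' @export
validate_summary_stats <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(canonical_stat_cols, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n_samples")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }

  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- why
  }
  flag(is.na(x$snp_id) | x$snp_id == "", "missing snp_id")
  flag(!(x$effect_allele %in% valid_bases), "invalid effect_allele")
  flag(!(x$other_allele %in% valid_bases), "invalid other_allele")
  flag(x$effect_allele == x$other_allele, "identical alleles")
  flag(is.na(x$pos) | x$pos < 1 | x$pos != round(x$pos), "invalid position")
  # eaf may be NA (flagged downstream), but if present must be in (0,1)
  bad_eaf <- !is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1)
  reason[is.na(reason) & bad_eaf] <- "eaf outside (0,1)"
  flag(is.na(x$beta), "missing beta")
  flag(is.na(x$se) | x$se <= 0, "non-positive se")
  flag(is.na(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1, "pvalue outside (0,1]")
  flag(is.na(x$n_samples) | x$n_samples < 1, "invalid n_samples")
  dup <- duplicated(x$snp_id) & is.na(reason)
  reason[dup] <- "duplicate snp_id"

  ok <- is.na(reason)
  rejects <- data.frame(row = which(!ok), snp_id = x$snp_id[!ok],
                        reason = reason[!ok], stringsAsFactors = FALSE)
  records <- x[ok, canonical_stat_cols, drop = FALSE]
  rownames(records) <- NULL
  list(records = records, rejects = rejects)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-delimited table with header, renames columns according to a
#' dialect, and validates each row. Invalid rows are dropped with a logged
#' reason, never silently coerced; the reject table is attached as the
#' `"rejects"` attribute and the counts are reported via `message()`.
#'
#' @param path Path to a tab-delimited file with header.
#' @param dialect Named character vector from [gwas_dialect()] or a preset.
#' @return data.frame of valid records in file order, with attribute
#'   `rejects`.
#' @export
read_summary_stats <- function(path, dialect = gwas_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  absent <- dialect[!(dialect %in% names(raw))]
  if (length(absent) > 0L) {
    stop("mapped column(s) not in header: ", paste(absent, collapse = ", "))
  }
  canon <- raw[, unname(dialect), drop = FALSE]
  names(canon) <- names(dialect)
  out <- validate_summary_stats(canon)
  message(sprintf("read_summary_stats: %d valid record(s), %d rejected row(s) [%s]",
                  nrow(out$records), nrow(out$rejects), basename(path)))
  if (nrow(out$rejects) > 0L) {
    message(paste(sprintf("  row %d (%s): %s", out$rejects$row,
                          out$rejects$snp_id, out$rejects$reason),
                  collapse = "\n"))
  }
  attr(out$records, "rejects") <- out$rejects
  out$records
}

#' Write a results table as tab-delimited text
#'
#' Writes any tabular result (a data.frame, or a list of data.frames sharing
#' one schema, which are row-bound) as TSV with a header row. Writing a set of
#' valid summary-statistic records and reading the file back reproduces the
#' records field-for-field.
#'
#' @param records data.frame or list of data.frames with identical columns.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_results_table <- function(records, path) {
  if (is.data.frame(records)) {
    tab <- records
  } else if (is.list(records) && all(vapply(records, is.data.frame, TRUE))) {
    schemas <- lapply(records, names)
    if (length(unique(vapply(schemas, paste, "", collapse = "\r"))) > 1L) {
      stop("records have mixed schemas; cannot write one table")
    }
    tab <- do.call(rbind, records)
  } else {
    stop("records must be a data.frame or a list of data.frames")
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open path for writing: ", path)
  })
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct and validate an LD matrix
#'
#' @param snp_ids Character vector of SNP identifiers (ordered).
#' @param r2 Square symmetric matrix of squared correlations in \[0,1\] with
#'   unit diagonal.
#' @return The r2 matrix with snp_ids as dimnames, class `ld_matrix`.
#' @export
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  n <- length(snp_ids)
  if (!all(dim(r2) == c(n, n))) stop("r2 must be ", n, "x", n)
  if (max(abs(r2 - t(r2))) > 1e-12) stop("r2 must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-12)) stop("r2 diagonal must be 1")
  if (any(r2 < 0 | r2 > 1)) stop("r2 entries must lie in [0,1]")
  dimnames(r2) <- list(snp_ids, snp_ids)
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' Read a square LD (r-squared) matrix from TSV
#'
#' Expects a header row of SNP ids and one column of SNP ids as the first
#' field; validated via [ld_matrix()].
#'
#' @param path Path to the TSV file.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  ld_matrix(ids, m)
}

#' Read a pathway membership table
#'
#' TSV with columns `pathway_id`, `pathway_name`, `members` (comma-joined
#' metabolite identifiers). Member sets must be non-empty and pathway_id
#' unique.
#'
#' @param path Path to the TSV file.
#' @return data.frame with a list-column `members`.
#' @export
read_pathway_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("pathway_id", "pathway_name", "members")
  if (!all(req %in% names(tab))) {
    stop("pathway table needs columns: ", paste(req, collapse = ", "))
  }
  tab$members <- lapply(strsplit(as.character(tab$members), ","), trimws)
  if (any(vapply(tab$members, length, 1L) == 0L) ||
      any(vapply(tab$members, function(m) all(m == ""), TRUE))) {
    stop("pathway member sets must be non-empty")
  }
  if (anyDuplicated(tab$pathway_id)) stop("pathway_id must be unique")
  tab
}

#' Read a SNP-to-trait annotation table
#'
#' TSV with columns `snp_id` and `trait` (free-text phenotype label), used for
#' confounder exclusion of instruments.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns snp_id, trait.
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("snp_id", "trait") %in% names(tab))) {
    stop("annotation table needs columns: snp_id, trait")
  }
  if (any(tab$snp_id == "" | tab$trait == "")) {
    stop("annotation fields must be non-empty")
  }
  tab[, c("snp_id", "trait")]
}
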