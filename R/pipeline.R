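#' Pipeline configuration
#'
#' One flat key/value object driving [run_screen()]. In `demo` mode a fully
#' seeded synthetic metabolite panel is generated in memory; in `files` mode
#' the paths must point to tab-delimited inputs (see [read_summary_stats()],
#' [read_ld_matrix()], [read_pathway_table()], [read_annotation_table()]).
#' Every threshold default equals the screening recipe's stated value:
#' exposure association p < 1e-5, clumping at r2 0.01 / 100 kb, F >= 10,
#' minimum 3 instruments, FDR and replication cutoffs at 0.05, and a
#' genome-wide 5e-8 instrument threshold for the reverse direction.
#'
#' @param mode `"demo"` or `"files"`.
#' @param seed Master integer seed; all stages derive their seeds from it.
#' @param n_exposures,n_causal,theta_causal,n_snps Demo panel shape.
#' @param exposure_path Path to the exposure TSV; must carry an `exposure_id`
#'   column in addition to the canonical summary-statistic columns.
#' @param outcome_path,replication_path Outcome cohort TSVs.
#' @param ld_path Square r-squared matrix TSV.
#' @param annotations_path,pathways_path Optional auxiliary tables.
#' @param p_threshold,clump_r2,clump_kb,f_min,min_snps,excluded_traits
#'   Instrument selection (see [selection_config()]).
#' @param reverse_p_threshold Instrument threshold for reverse MR.
#' @param sd_trait Exposure trait SD for [f_statistic()]; the demo panel is on
#'   the standardized scale, hence 1.
#' @param n_boot Bootstrap draws for median/mode standard errors.
#' @param presso_n_sim MR-PRESSO simulated null draws.
#' @param fdr_threshold,suggestive_p,meta_alpha Tiering and candidacy cutoffs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("demo", "files"), seed = 42,
                            n_exposures = 50, n_causal = 3,
                            theta_causal = 0.5, n_snps = 30,
                            exposure_path = NULL, outcome_path = NULL,
                            replication_path = NULL, ld_path = NULL,
                            annotations_path = NULL, pathways_path = NULL,
                            p_threshold = 1e-5, clump_r2 = 0.01,
                            clump_kb = 100, f_min = 10, min_snps = 3,
                            excluded_traits = c("body mass index",
                                                "body weight", "hypertension",
                                                "diastolic blood pressure",
                                                "interstitial lung disease"),
                            reverse_p_threshold = 5e-8, sd_trait = 1,
                            n_boot = 1000, presso_n_sim = 1000,
                            fdr_threshold = 0.05, suggestive_p = 0.05,
                            meta_alpha = 0.05) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

new_run_log <- function() new.env(parent = emptyenv())

log_stage <- function(log, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  log$entries <- c(log$entries, list(entry))
  invisible(entry)
}

write_run_log <- function(log, path) {
  lines <- vapply(log$entries, function(e) {
    jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
}

# Demo pathway library over exposure ids: one pathway holding the planted
# causal metabolites (plus filler) and several random ones.
demo_pathways <- function(exposure_ids, causal_ids, seed) {
  with_seed(seed, {
    rest <- setdiff(exposure_ids, causal_ids)
    p1 <- c(causal_ids, sample(rest, min(6, length(rest))))
    size <- min(10, max(2, length(exposure_ids) %/% 2))
    others <- lapply(1:4, function(i) sample(exposure_ids, size))
    data.frame(
      pathway_id = sprintf("pw_%02d", 1:5),
      pathway_name = c("vitamin cofactor metabolism", sprintf("pathway %d", 2:5)),
      members = I(c(list(p1), others)),
      stringsAsFactors = FALSE)
  })
}

load_screen_inputs <- function(config, log) {
  if (config$mode == "demo") {
    sim <- simulate_screen_panel(
      n_exposures = config$n_exposures, n_causal = config$n_causal,
      theta_causal = config$theta_causal, seed = config$seed,
      n_snps = config$n_snps)
    exposures <- lapply(sim$panels, `[[`, "exposure")
    outcomes <- lapply(sim$panels, function(p) p$outcomes[[1]])
    replications <- lapply(sim$panels, function(p) {
      if (length(p$outcomes) >= 2) p$outcomes[[2]] else NULL
    })
    lds <- lapply(sim$panels, `[[`, "ld")
    ld_scores <- lapply(sim$panels, `[[`, "ld_scores")
    causal_ids <- sim$truth_table$exposure_id[sim$truth_table$causal]
    pathways <- demo_pathways(names(sim$panels), causal_ids,
                              config$seed + 777L)
    log_stage(log, "load_inputs", mode = "demo",
              n_exposures = length(exposures),
              planted_causal = causal_ids)
    list(exposures = exposures, outcomes = outcomes,
         replications = replications, lds = lds, ld_scores = ld_scores,
         annotations = NULL, pathways = pathways,
         truth_table = sim$truth_table)
  } else {
    for (p in c(config$exposure_path, config$outcome_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("load_inputs: missing input file: ",
             if (is.null(p)) "(unset path)" else p)
      }
    }
    exp_tab <- utils::read.delim(config$exposure_path, sep = "\t",
                                 stringsAsFactors = FALSE)
    if (!"exposure_id" %in% names(exp_tab)) {
      stop("exposure table must carry an exposure_id column")
    }
    split_exp <- split(exp_tab[, setdiff(names(exp_tab), "exposure_id")],
                       exp_tab$exposure_id)
    exposures <- lapply(split_exp, function(x) validate_summary_stats(x)$records)
    outcome <- read_summary_stats(config$outcome_path)
    replication <- if (!is.null(config$replication_path)) {
      read_summary_stats(config$replication_path)
    } else NULL
    ld <- if (!is.null(config$ld_path)) read_ld_matrix(config$ld_path) else {
      stop("files mode requires ld_path")
    }
    annotations <- if (!is.null(config$annotations_path)) {
      read_annotation_table(config$annotations_path)
    } else NULL
    pathways <- if (!is.null(config$pathways_path)) {
      read_pathway_table(config$pathways_path)
    } else NULL
    scores <- data.frame(snp_id = rownames(ld), ld_score = rowSums(ld),
                         stringsAsFactors = FALSE)
    log_stage(log, "load_inputs", mode = "files",
              n_exposures = length(exposures))
    list(exposures = exposures,
         outcomes = rep(list(outcome), length(exposures)),
         replications = rep(list(replication), length(exposures)),
         lds = rep(list(ld), length(exposures)),
         ld_scores = rep(list(scores), length(exposures)),
         annotations = annotations, pathways = pathways, truth_table = NULL)
  }
}

# Selection + harmonization + full estimator suite for one exposure.
analyze_exposure <- function(id, exposure, outcome, ld, config, annotations,
                             seed) {
  sel_cfg <- selection_config(
    p_threshold = config$p_threshold, clump_r2 = config$clump_r2,
    clump_kb = config$clump_kb, f_min = config$f_min,
    min_snps = config$min_snps, excluded_traits = config$excluded_traits)
  sel <- select_instruments(exposure, ld, sel_cfg, annotations = annotations,
                            sd_trait = config$sd_trait)
  if (sel$status != "ok") {
    return(list(id = id, status = "too_few_instruments", selection = sel))
  }
  h <- harmonize(sel$records, outcome)
  if (nrow(h$instruments) < config$min_snps) {
    return(list(id = id, status = "too_few_instruments", selection = sel,
                harmonization = h))
  }
  res <- run_all_methods(h$instruments, seed = seed, n_boot = config$n_boot)
  list(id = id, status = "ok", selection = sel, harmonization = h,
       instruments = h$instruments, results = res,
       primary = res[res$method == attr(res, "primary"), ])
}

#' Run the full panel screen
#'
#' Executes the complete screening pipeline in order: instrument selection,
#' harmonization, all five estimators, sensitivity diagnostics, FDR tiering,
#' confounder-exclusion rerun of non-null exposures, replication, direction
#' consistency and fixed-effect meta-analysis, cross-trait LD score regression
#' on the candidates, reverse MR on the candidates, and pathway
#' over-representation of the nominally associated metabolites. Identical
#' config and seed yield identical outputs; when `out_dir` is given, all
#' result tables are written as TSV alongside a JSON-lines run log.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return list: `panel` (the per-exposure screen table), `mr_results` (all
#'   methods, all exposures), `sensitivity`, `instruments`,
#'   `exclusion_report`, `ldsc`, `reverse`, `enrichment`, `log`.
#' @export
#' @examples
#' \donttest{
#' res <- run_screen(pipeline_config(mode = "demo", n_exposures = 8,
#'                                   n_causal = 1, presso_n_sim = 200,
#'                                   n_boot = 200))
#' subset(res$panel, candidate)
#' }
run_screen <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- new_run_log()
  inputs <- load_screen_inputs(config, log)
  ids <- names(inputs$exposures)

  # stage 1-3: select -> harmonize -> estimate (no confounder exclusion yet)
  first_cfg <- config
  first_cfg$excluded_traits <- character(0)
  analyses <- lapply(seq_along(ids), function(i) {
    analyze_exposure(ids[i], inputs$exposures[[i]], inputs$outcomes[[i]],
                     inputs$lds[[i]], first_cfg, annotations = NULL,
                     seed = config$seed + i)
  })
  names(analyses) <- ids
  ok <- vapply(analyses, function(a) a$status == "ok", TRUE)
  log_stage(log, "select_harmonize_estimate", analyzed = sum(ok),
            excluded_too_few = ids[!ok])

  # stage 4: sensitivity diagnostics
  sens <- lapply(analyses[ok], function(a) {
    sensitivity_report(a$instruments, n_sim = config$presso_n_sim,
                       seed = config$seed + match(a$id, ids))
  })
  log_stage(log, "sensitivity", n = length(sens))

  primary <- do.call(rbind, lapply(analyses[ok], function(a) {
    cbind(data.frame(exposure_id = a$id, stringsAsFactors = FALSE),
          a$primary)
  }))
  rownames(primary) <- NULL

  # stage 5: FDR and tiers over the whole analyzed family
  tiers <- screen_panel(primary, replication = NULL,
                        fdr_threshold = config$fdr_threshold,
                        p_threshold = config$suggestive_p,
                        meta_alpha = config$meta_alpha)
  log_stage(log, "fdr_tiering",
            significant = sum(tiers$tier == "significant"),
            suggestive = sum(tiers$tier == "suggestive"))

  # stage 6: confounder-exclusion rerun for exposures reaching tier != null
  rerun_ids <- tiers$exposure_id[tiers$tier != "null"]
  if (!is.null(inputs$annotations) && length(config$excluded_traits) > 0L) {
    for (id in rerun_ids) {
      i <- match(id, ids)
      redo <- analyze_exposure(id, inputs$exposures[[i]],
                               inputs$outcomes[[i]], inputs$lds[[i]], config,
                               annotations = inputs$annotations,
                               seed = config$seed + i)
      analyses[[id]] <- redo
      if (redo$status == "ok") {
        sens[[id]] <- sensitivity_report(redo$instruments,
                                         n_sim = config$presso_n_sim,
                                         seed = config$seed + i)
      }
    }
    ok <- vapply(analyses, function(a) a$status == "ok", TRUE)
    primary <- do.call(rbind, lapply(analyses[ok], function(a) {
      cbind(data.frame(exposure_id = a$id, stringsAsFactors = FALSE),
            a$primary)
    }))
    rownames(primary) <- NULL
    log_stage(log, "confounder_rerun", rerun = rerun_ids,
              still_analyzed = sum(ok))
  } else {
    log_stage(log, "confounder_rerun", rerun = character(0),
              note = "no annotation table or no excluded traits")
  }

  # stage 7: replication of non-null exposures on the second cohort
  replication <- NULL
  rep_rows <- list()
  for (id in intersect(rerun_ids, names(analyses)[ok])) {
    i <- match(id, ids)
    rep_out <- inputs$replications[[i]]
    if (is.null(rep_out)) next
    h <- harmonize(analyses[[id]]$selection$records, rep_out)
    if (nrow(h$instruments) < 2L) next
    fit <- ivw(h$instruments)
    rep_rows[[id]] <- cbind(data.frame(exposure_id = id,
                                       stringsAsFactors = FALSE), fit)
  }
  if (length(rep_rows) > 0L) replication <- do.call(rbind, rep_rows)
  log_stage(log, "replication", replicated = length(rep_rows))

  # stage 8: direction consistency + fixed-effect meta-analysis
  panel <- screen_panel(primary, replication = replication,
                        fdr_threshold = config$fdr_threshold,
                        p_threshold = config$suggestive_p,
                        meta_alpha = config$meta_alpha)
  if (!is.null(inputs$truth_table)) {
    panel$true_theta <- inputs$truth_table$theta[
      match(panel$exposure_id, inputs$truth_table$exposure_id)]
  }
  candidates <- panel$exposure_id[panel$candidate]
  log_stage(log, "meta_direction", candidates = candidates)

  # stage 9: cross-trait LDSC on the candidates
  ldsc_rows <- lapply(candidates, function(id) {
    i <- match(id, ids)
    ex <- inputs$exposures[[i]]
    ou <- inputs$outcomes[[i]]
    shared <- intersect(ex$snp_id, ou$snp_id)
    scores <- inputs$ld_scores[[i]]
    l <- scores$ld_score[match(shared, scores$snp_id)]
    if (length(shared) < 40L) {
      return(data.frame(exposure_id = id, rg = NA_real_, se = NA_real_,
                        pvalue = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    fit <- cross_trait_ldsc(
      z1 = ex$beta[match(shared, ex$snp_id)] / ex$se[match(shared, ex$snp_id)],
      z2 = ou$beta[match(shared, ou$snp_id)] / ou$se[match(shared, ou$snp_id)],
      ld_scores = l, n1 = ex$n_samples[1], n2 = ou$n_samples[1],
      n_blocks = min(20L, length(shared) %/% 2L))
    data.frame(exposure_id = id, rg = fit$rg, se = fit$se,
               pvalue = fit$pvalue, flagged = fit$flagged,
               stringsAsFactors = FALSE)
  })
  ldsc_tab <- if (length(ldsc_rows) > 0L) do.call(rbind, ldsc_rows) else NULL
  log_stage(log, "ldsc", n = length(ldsc_rows))

  # stage 10: reverse MR on the candidates
  rev_rows <- lapply(candidates, function(id) {
    i <- match(id, ids)
    rev <- run_reverse_mr(inputs$outcomes[[i]], inputs$exposures[[i]],
                          inputs$lds[[i]], config,
                          seed = config$seed + 100000L + i)
    if (rev$status == "reverse_untestable") {
      data.frame(exposure_id = id, status = "reverse_untestable",
                 method = NA_character_, n_snp = NA_integer_,
                 beta = NA_real_, se = NA_real_, pvalue = NA_real_,
                 passes = NA, stringsAsFactors = FALSE)
    } else {
      cbind(data.frame(exposure_id = id, status = "ok",
                       stringsAsFactors = FALSE),
            rev$results[, c("method", "n_snp", "beta", "se", "pvalue")],
            passes = all(rev$results$pvalue >= 0.05))
    }
  })
  rev_tab <- if (length(rev_rows) > 0L) do.call(rbind, rev_rows) else NULL
  log_stage(log, "reverse_mr", n = length(rev_rows))

  # stage 11: pathway over-representation of nominally associated metabolites
  enrichment <- NULL
  if (!is.null(inputs$pathways)) {
    nominal <- panel$exposure_id[panel$pvalue < 0.05]
    if (length(nominal) > 0L) {
      enrichment <- enrich(nominal, inputs$pathways, panel$exposure_id)
    }
    log_stage(log, "enrichment", candidates = length(nominal))
  }

  mr_results <- do.call(rbind, lapply(analyses[ok], function(a) {
    cbind(data.frame(exposure_id = a$id, stringsAsFactors = FALSE),
          a$results)
  }))
  rownames(mr_results) <- NULL
  sens_tab <- do.call(rbind, lapply(names(sens), function(id) {
    s <- sens[[id]]
    data.frame(
      exposure_id = id,
      q_stat = if (!is.null(s$q)) s$q$q_stat else NA_real_,
      q_df = if (!is.null(s$q)) s$q$q_df else NA_integer_,
      q_pvalue = if (!is.null(s$q)) s$q$q_pvalue else NA_real_,
      heterogeneity_flag = if (!is.null(s$q)) s$q$heterogeneity_flag else NA,
      egger_intercept = if (!is.null(s$egger)) s$egger$intercept else NA_real_,
      egger_intercept_se = if (!is.null(s$egger)) s$egger$se else NA_real_,
      egger_intercept_pvalue = if (!is.null(s$egger)) s$egger$pvalue else NA_real_,
      presso_global_pvalue = if (!is.null(s$presso)) s$presso$global_pvalue else NA_real_,
      presso_n_outliers = if (!is.null(s$presso)) length(s$presso$outlier_ids) else NA_integer_,
      presso_distortion_pvalue = if (!is.null(s$presso)) s$presso$distortion_pvalue else NA_real_,
      stringsAsFactors = FALSE)
  }))
  instruments <- do.call(rbind, lapply(analyses[ok], function(a) {
    cbind(data.frame(exposure_id = a$id, stringsAsFactors = FALSE),
          a$instruments)
  }))
  exclusion_report <- do.call(rbind, lapply(analyses, function(a) {
    if (nrow(a$selection$report) == 0L) return(NULL)
    cbind(data.frame(exposure_id = a$id, stringsAsFactors = FALSE),
          a$selection$report)
  }))

  out <- list(panel = panel, mr_results = mr_results,
              sensitivity = sens_tab, instruments = instruments,
              exclusion_report = exclusion_report, ldsc = ldsc_tab,
              reverse = rev_tab, enrichment = enrichment,
              loo = lapply(sens, `[[`, "loo"), log = log$entries)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tabs <- c("panel", "mr_results", "sensitivity", "instruments",
              "exclusion_report", "ldsc", "reverse", "enrichment")
    for (tb in tabs) {
      if (!is.null(out[[tb]])) {
        write_results_table(out[[tb]], file.path(out_dir,
                                                 paste0(tb, ".tsv")))
      }
    }
    write_run_log(log, file.path(out_dir, "run_log.jsonl"))
  }
  out
}

#' Reverse-direction MR for one exposure-outcome pair
#'
#' Swaps the roles: instruments are selected from the disease GWAS at the
#' (stricter, genome-wide) `reverse_p_threshold`, harmonized against the
#' metabolite GWAS as the outcome, and fed to the estimator suite. A candidate
#' "passes" the reverse check when no reverse estimate reaches p < 0.05. When
#' too few reverse instruments are selectable the pair is flagged
#' `reverse_untestable` rather than erroring (rare binary traits often lack
#' genome-wide hits).
#'
#' @param disease_stats Summary statistics of the original outcome (now the
#'   exposure).
#' @param metabolite_stats Summary statistics of the original exposure (now
#'   the outcome).
#' @param ld An [ld_matrix()] covering the disease records.
#' @param config A [pipeline_config()] supplying thresholds.
#' @param seed Integer seed for the estimator bootstraps.
#' @return list: `status` ("ok" or "reverse_untestable"), `results`
#'   (MR-result data.frame when testable), `selection`.
#' @export
run_reverse_mr <- function(disease_stats, metabolite_stats, ld,
                           config = pipeline_config(), seed = 1) {
  sel_cfg <- selection_config(
    p_threshold = config$reverse_p_threshold, clump_r2 = config$clump_r2,
    clump_kb = config$clump_kb, f_min = config$f_min,
    min_snps = 1, excluded_traits = character(0))
  sel <- select_instruments(disease_stats, ld, sel_cfg,
                            sd_trait = config$sd_trait)
  if (nrow(sel$records) < 1L) {
    return(list(status = "reverse_untestable", results = NULL,
                selection = sel))
  }
  h <- harmonize(sel$records, metabolite_stats)
  if (nrow(h$instruments) < 1L) {
    return(list(status = "reverse_untestable", results = NULL,
                selection = sel))
  }
  res <- run_all_methods(h$instruments, seed = seed, n_boot = config$n_boot)
  list(status = "ok", results = res, selection = sel)
}
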