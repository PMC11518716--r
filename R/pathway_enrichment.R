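#' Pathway over-representation analysis
#'
#' Hypergeometric upper-tail test of each pathway's overlap with a candidate
#' metabolite set: `P(X >= overlap)` with population `universe_size`,
#' successes `pathway_size` (members intersected with the universe), draws
#' `candidate_count`. Equivalent to a one-sided Fisher exact test on the 2x2
#' table.
#'
#' @param candidates Character vector of candidate metabolite ids (must be a
#'   subset of the universe).
#' @param pathways Pathway table from [read_pathway_table()] (or a data.frame
#'   with `pathway_id`, `pathway_name` and a `members` list-column).
#' @param universe Character vector: all metabolites eligible for candidacy.
#' @return data.frame sorted by p-value (ties by pathway_id): pathway_id,
#'   pathway_name, overlap_count, pathway_size, candidate_count,
#'   universe_size, pvalue.
#' @export
enrich <- function(candidates, pathways, universe) {
  candidates <- unique(candidates)
  universe <- unique(universe)
  outside <- setdiff(candidates, universe)
  if (length(outside) > 0L) {
    stop("candidate(s) outside universe: ", paste(outside, collapse = ", "))
  }
  n_cand <- length(candidates)
  n_univ <- length(universe)
  rows <- lapply(seq_len(nrow(pathways)), function(i) {
    members <- intersect(pathways$members[[i]], universe)
    k <- length(intersect(members, candidates))
    p <- if (k == 0L) 1 else {
      stats::phyper(k - 1, length(members), n_univ - length(members), n_cand,
                    lower.tail = FALSE)
    }
    data.frame(pathway_id = pathways$pathway_id[i],
               pathway_name = pathways$pathway_name[i],
               overlap_count = k, pathway_size = length(members),
               candidate_count = n_cand, universe_size = n_univ,
               pvalue = min(max(p, .Machine$double.xmin), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pvalue, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
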