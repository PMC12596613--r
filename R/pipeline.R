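#' Consensus voting pathway enrichment
#'
#' End-to-end driver: builds the (k, e, d) parameter grid, materializes one
#' gene-list candidate per grid cell through the eQTM mapping, prunes each k
#' pool with the entropy-based composite score and greedy Jaccard selection,
#' runs hypergeometric enrichment on every surviving list, retains pathways
#' stable across runs, and aggregates them by calibrated harmonic-mean-p
#' voting with Benjamini-Hochberg adjustment.
#'
#' The enrichment universe is the set of genes present in both the eQTM
#' resource and the pathway database - the genes the pipeline can actually
#' reach - so unreachable genes cannot manufacture enrichment.
#'
#' @param ewas an [ewas_results] object.
#' @param eqtm an `eqtm` resource ([create_eqtm()]).
#' @param db a [pathway_db].
#' @param n_k,n_e,n_d grid densities (default 5 each).
#' @param k_values optional explicit top-k values (required when the ranking
#'   metric is not a p-value).
#' @param jaccard_threshold greedy pruning overlap threshold (default 0.7).
#' @param min_votes,min_count pathway stability filters (defaults 2 and 2).
#' @param run_p_cutoff within-run BH-adjusted p cutoff for a pathway to
#'   count as appearing in a run (default 0.05; see [prune_pathways()]).
#' @param alpha FDR level anchoring the k grid (default 0.05).
#' @return Object of class `pathway_vote_result`: list with `vote_table`,
#'   `grid`, `survivors` (per k), `candidates` (per k), `universe`,
#'   `diagnostics` (per-k score tables), `config`.
#' @export
pathway_vote <- function(ewas, eqtm, db, n_k = 5, n_e = 5, n_d = 5,
                         k_values = NULL, jaccard_threshold = 0.7,
                         min_votes = 2, min_count = 2, run_p_cutoff = 0.05,
                         alpha = 0.05) {
  stopifnot(inherits(ewas, "ewas_results"), inherits(eqtm, "eqtm"),
            inherits(db, "pathway_db"))
  universe <- intersect(unique(eqtm$pairs$gene),
                        unique(unlist(db$genesets, use.names = FALSE)))
  if (!length(universe))
    stopf("no genes shared between the eQTM resource and the pathway database")
  grid <- build_grid(ewas, eqtm, n_k, n_e, n_d, k_values = k_values, alpha = alpha)
  candidates <- generate_candidates(ewas, eqtm, grid)
  pools <- lapply(candidates, build_pool, eqtm = eqtm)
  diagnostics <- lapply(pools, composite_scores)
  survivors <- lapply(pools, prune_pool, jaccard_threshold = jaccard_threshold)

  index <- ora_index(db, universe)
  records <- do.call(rbind, unlist(lapply(survivors, function(cands)
    lapply(cands, ora_enrich, db = db, universe = universe, index = index)),
    recursive = FALSE))
  if (is.null(records)) records <- ora_enrich(character(0), db, universe,
                                              run_id = "none", index = index)
  surviving <- prune_pathways(records, min_votes = min_votes,
                              min_count = min_count, run_p_cutoff = run_p_cutoff)
  vt <- aggregate_votes(surviving, db)
  structure(list(vote_table = vt, grid = grid, survivors = survivors,
                 candidates = candidates, universe = universe,
                 diagnostics = diagnostics,
                 config = list(n_k = n_k, n_e = n_e, n_d = n_d,
                               k_values = grid$k_values,
                               jaccard_threshold = jaccard_threshold,
                               min_votes = min_votes, min_count = min_count,
                               run_p_cutoff = run_p_cutoff, alpha = alpha)),
            class = "pathway_vote_result")
}

#' @export
print.pathway_vote_result <- function(x, ...) {
  cat(sprintf("pathway_vote_result: %d pathways retained (%d at q < 0.05)\n",
              nrow(x$vote_table), sum(x$vote_table$q_bh < 0.05)))
  cat(sprintf("  grid: k = {%s}; %d survivors across %d pools\n",
              paste(x$grid$k_values, collapse = ", "),
              sum(lengths(x$survivors)), length(x$survivors)))
  if (nrow(x$vote_table)) {
    top <- utils::head(as.data.frame(x$vote_table)[
      c("pathway_id", "votes", "hmp", "calibrated_p", "q_bh")], 5)
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Lower bound on the number of non-null tests
#'
#' Counts p-values in excess of the uniform null expectation with a
#' normal-fluctuation guard (a Meinshausen-Rice-type lower bound): over a
#' threshold grid t, the estimate is
#' `max_t floor(#\{p <= t\} - n t - z_conf * sqrt(n t (1 - t)))`, floored at 0.
#' Under a pure null the estimate is almost always 0; with genuine signal it
#' approaches the true non-null count. Useful to anchor the top-k grid when
#' the Benjamini-Hochberg count sits at its detection boundary.
#'
#' @param pvals numeric p-values in `(0, 1]` (or an [ewas_results] object
#'   with p-value metric).
#' @param conf guard level for the uniform-null fluctuation (default 0.999).
#' @return non-negative integer.
#' @export
estimate_signal_count <- function(pvals, conf = 0.999) {
  if (inherits(pvals, "ewas_results")) {
    if (pvals$metric_kind != "pvalue")
      stopf("estimate_signal_count needs p-values")
    pvals <- pvals$data$metric
  }
  n <- length(pvals)
  tg <- sort(unique(c(10^seq(-6, -0.3, length.out = 60), seq(0.05, 0.95, by = 0.05))))
  ct <- vapply(tg, function(t) sum(pvals <= t), 0L)
  excess <- ct - n * tg - stats::qnorm(conf) * sqrt(n * tg * (1 - tg))
  max(0L, as.integer(floor(max(excess))))
}
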