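#' Classical nearest-gene enrichment baseline
#'
#' The conventional comparator pipeline: take the top-k ranked CpGs (same
#' ranking and tie rules as the consensus pipeline), map each to its single
#' annotated gene, and run one hypergeometric enrichment pass against the
#' database with the universe restricted to annotated genes present in the
#' database, followed by Benjamini-Hochberg adjustment.
#'
#' @param ewas an [ewas_results] object.
#' @param annotation named character vector mapping cpg id to its single
#'   annotated gene ([read_annotation()]).
#' @param db a [pathway_db].
#' @param k number of top CpGs; defaults to the FDR-significant CpG count
#'   (requires a p-value metric).
#' @param alpha FDR level for the default k.
#' @return data.frame of class `baseline_result`: `pathway_id`, `name`,
#'   `p_raw`, `q_bh`, `overlap_count`, `pathway_size`, plus list column
#'   `gene_hits`; ordered by `q_bh`, `p_raw`, `pathway_id`.
#' @export
classical_enrich <- function(ewas, annotation, db, k = NULL, alpha = 0.05) {
  stopifnot(inherits(ewas, "ewas_results"), inherits(db, "pathway_db"))
  if (is.null(names(annotation)) || anyNA(names(annotation)))
    stopf("annotation must be a named character vector (cpg -> gene)")
  if (is.null(k)) k <- count_fdr_significant(ewas, alpha)
  empty <- data.frame(pathway_id = character(0), name = character(0),
                      p_raw = numeric(0), q_bh = numeric(0),
                      overlap_count = integer(0), pathway_size = integer(0))
  empty$gene_hits <- list()
  class(empty) <- c("baseline_result", "data.frame")
  if (k < 1) {
    warnf("no top-ranked CpGs to annotate (k = %d)", k)
    return(empty)
  }
  topk <- top_k_cpgs(ewas, min(k, nrow(ewas$data)))
  genes <- unique(unname(annotation[topk]))
  genes <- genes[!is.na(genes)]
  universe <- intersect(unique(unname(annotation)),
                        unique(unlist(db$genesets, use.names = FALSE)))
  if (!length(genes) || !length(intersect(genes, universe))) {
    warnf("no annotated genes among the top-%d CpGs", k)
    return(empty)
  }
  rec <- ora_enrich(genes, db, universe, run_id = "classical")
  if (!nrow(rec)) return(empty)
  out <- data.frame(pathway_id = rec$pathway_id,
                    name = unname(db$pathway_names[rec$pathway_id]),
                    p_raw = rec$p_raw,
                    q_bh = stats::p.adjust(rec$p_raw, method = "BH"),
                    overlap_count = rec$overlap_count,
                    pathway_size = rec$path_K,
                    stringsAsFactors = FALSE)
  out$gene_hits <- rec$gene_hits
  out <- out[order(out$q_bh, out$p_raw, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("baseline_result", "data.frame")
  out
}
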