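#' Upper-tail hypergeometric probability
#'
#' P(X >= x) where X counts pathway members in a drawn gene list:
#' X ~ Hypergeometric(universe size N, pathway size K, list size n). Exact,
#' via the stable tail routine in `stats::phyper`.
#'
#' @param x observed overlap (0 <= x <= min(list_n, path_K)).
#' @param list_n gene-list size within the universe.
#' @param path_K pathway size within the universe.
#' @param universe_N universe size.
#' @return scalar in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(x, list_n, path_K, universe_N) {
  if (any(c(x, list_n, path_K, universe_N) < 0) ||
      list_n > universe_N || path_K > universe_N || x > min(list_n, path_K))
    stopf("inconsistent hypergeometric sizes: x=%s n=%s K=%s N=%s",
          format(x), format(list_n), format(path_K), format(universe_N))
  stats::phyper(x - 1, path_K, universe_N - path_K, list_n, lower.tail = FALSE)
}

# Precompute universe-restricted pathway membership for repeated ORA runs.
ora_index <- function(db, universe) {
  sets <- lapply(db$genesets, function(g) g[g %in% universe])
  sizes <- vapply(sets, length, 0L)
  keep <- sizes > 0L
  list(sets = sets[keep], sizes = sizes[keep], universe_n = length(universe))
}

#' Over-representation analysis of one gene list
#'
#' Standard hypergeometric enrichment of a candidate gene list against every
#' pathway in the database. Both the list and the pathway gene sets are
#' restricted to the universe before testing; pathways with zero overlap
#' produce no record.
#'
#' @param candidate a candidate (list with `genes`, `k`, `e_thr`, `d_thr`) or
#'   a plain character vector of genes.
#' @param db a [pathway_db] object.
#' @param universe character vector: the gene universe (for the consensus
#'   pipeline, genes present in both the eQTM resource and the database).
#' @param run_id identifier of this enrichment run (defaults to the
#'   candidate's grid cell).
#' @param index optional precomputed internal index (repeated calls).
#' @return data.frame with one row per overlapping pathway: `pathway_id`,
#'   `run_id`, `p_raw`, `overlap_count`, `gene_hits` (list column),
#'   `path_K`, `list_n`, `universe_N`.
#' @export
ora_enrich <- function(candidate, db, universe, run_id = NULL, index = NULL) {
  genes <- if (is.character(candidate)) candidate else candidate$genes
  if (is.null(run_id)) {
    run_id <- if (is.character(candidate)) "run"
    else sprintf("k=%d|e=%.8g|d=%.8g", candidate$k, candidate$e_thr, candidate$d_thr)
  }
  if (!length(universe)) stopf("empty gene universe")
  if (is.null(index)) index <- ora_index(db, universe)
  genes <- unique(genes[genes %in% universe])
  empty <- data.frame(pathway_id = character(0), run_id = character(0),
                      p_raw = numeric(0), overlap_count = integer(0),
                      path_K = integer(0), list_n = integer(0),
                      universe_N = integer(0))
  empty$gene_hits <- list()
  if (!length(genes)) {
    warnf("gene list '%s' is empty after universe intersection", run_id)
    return(empty)
  }
  hits <- lapply(index$sets, function(s) s[s %in% genes])
  ov <- vapply(hits, length, 0L)
  keep <- ov >= 1L
  if (!any(keep)) return(empty)
  ids <- names(index$sets)[keep]
  res <- data.frame(pathway_id = ids, run_id = run_id,
                    p_raw = stats::phyper(ov[keep] - 1L, index$sizes[keep],
                                          index$universe_n - index$sizes[keep],
                                          length(genes), lower.tail = FALSE),
                    overlap_count = ov[keep],
                    path_K = index$sizes[keep], list_n = length(genes),
                    universe_N = index$universe_n,
                    row.names = NULL, stringsAsFactors = FALSE)
  res$gene_hits <- unname(hits[keep])
  res
}

#' Retain pathways that are stable across enrichment runs
#'
#' A pathway "appears" in a run when it is part of that run's standard
#' enrichment output: within each run, p-values are Benjamini-Hochberg
#' adjusted across the run's tested pathways and only records with adjusted
#' p below `run_p_cutoff` count (the convention of standard enrichment
#' tools; the adjustment gates membership only - raw p-values are what the
#' harmonic mean later combines). Records must further reach the minimum
#' overlap (`min_count`), and a pathway is retained when at least
#' `min_votes` distinct runs remain; the count filter is applied before
#' counting votes (the stricter order). Set `run_p_cutoff = 1` to make every
#' overlapping pathway count as an appearance.
#'
#' @param records row-bound [ora_enrich()] records across all runs.
#' @param min_votes minimum distinct runs per pathway (default 2).
#' @param min_count minimum overlap genes per record (default 2).
#' @param run_p_cutoff within-run BH-adjusted p cutoff for a record to count
#'   as an appearance (default 0.05).
#' @return data.frame of surviving records (same columns as the input).
#' @export
prune_pathways <- function(records, min_votes = 2, min_count = 2,
                           run_p_cutoff = 0.05) {
  if (min_votes < 2) stopf("min_votes must be at least 2 (multiple enrichment runs)")
  if (!nrow(records)) return(records)
  rec <- records
  if (run_p_cutoff < 1) {
    adj <- stats::ave(rec$p_raw, rec$run_id,
                      FUN = function(p) stats::p.adjust(p, method = "BH"))
    rec <- rec[adj < run_p_cutoff, , drop = FALSE]
  }
  rec <- rec[rec$overlap_count >= min_count, , drop = FALSE]
  if (!nrow(rec)) return(rec)
  votes <- tapply(rec$run_id, rec$pathway_id, function(r) length(unique(r)))
  keep_ids <- names(votes)[votes >= min_votes]
  out <- rec[rec$pathway_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonic mean p-value
#'
#' Weighted harmonic mean of p-values, `sum(w) / sum(w / p)`; weights default
#' to equal. The harmonic mean heavily favors the smallest p-values and is
#' robust to positive dependence among the combined tests.
#'
#' @param pvals p-values in `(0, 1]`.
#' @param weights positive weights (default equal).
#' @return scalar.
#' @export
harmonic_mean_p <- function(pvals, weights = NULL) {
  if (!length(pvals)) stopf("no p-values to combine")
  if (any(pvals <= 0) || any(pvals > 1)) stopf("p-values must lie in (0,1]")
  if (is.null(weights)) weights <- rep(1, length(pvals))
  if (length(weights) != length(pvals) || any(weights <= 0))
    stopf("weights must be positive and match the p-values in length")
  sum(weights) / sum(weights / pvals)
}

# P(Z > x) for Z ~ stable(alpha = 1, beta = 1), standard S0 parametrization,
# via Nolan's (1997) non-oscillatory integral representation. The integrand
# is bounded in [0,1]; computing 1 - exp(.) directly keeps small tails exact.
stable11_upper_tail <- function(x) {
  if (!is.finite(x)) return(if (x > 0) 0 else 1)
  w <- exp(-pi * x / 2)
  f <- function(th) {
    v <- (2 / pi) * ((pi / 2 + th) / cos(th)) * exp((pi / 2 + th) * tan(th))
    r <- -expm1(-w * v)
    r[!is.finite(v)] <- 1  # V(theta) overflows near pi/2: integrand saturates at 1
    r
  }
  val <- stats::integrate(f, -pi / 2, pi / 2, rel.tol = 1e-10, abs.tol = 1e-14,
                          subdivisions = 500L, stop.on.error = FALSE)$value
  min(1, max(0, val / pi))
}

#' Calibrate a harmonic mean p-value
#'
#' Converts a harmonic mean of L p-values into an asymptotically exact
#' combined p-value that remains valid under positive dependence among the
#' combined tests: under the null, the reciprocal of the harmonic mean
#' follows a Landau distribution (the alpha = 1, beta = 1 stable law) with
#' location `log(L) + 0.874367040387922` and scale `pi/2`; the calibrated
#' value is that distribution's upper tail at `1/hmp`. A single test (L = 1)
#' is returned unchanged.
#'
#' @param hmp harmonic mean p-value in `(0, 1]`.
#' @param L number of tests combined (the vote count).
#' @return calibrated p-value in `(0, 1]`.
#' @export
calibrate_hmp <- function(hmp, L) {
  if (!is_count(L)) stopf("L must be a positive integer")
  if (hmp <= 0 || hmp > 1) stopf("hmp must lie in (0,1]")
  if (L == 1L) return(hmp)
  mu <- log(L) + 0.874367040387922
  # standard S0 stable(1,1) after removing location and the scale's log-shift
  z <- (1 / hmp - mu) * 2 / pi
  p <- stable11_upper_tail(z)
  # the asymptotic tail can undershoot the identity near hmp = 1; a combined
  # p-value is never smaller than the harmonic mean it calibrates
  min(1, max(p, hmp, .Machine$double.xmin))
}

#' Aggregate surviving enrichment records into a vote table
#'
#' Per pathway: votes = number of surviving records, the harmonic mean of
#' their raw enrichment p-values (equal weights), the calibrated combined
#' p-value (L = the pathway's own vote count), and the union of overlap
#' genes. Calibrated p-values are then Benjamini-Hochberg adjusted across all
#' retained pathways. Rows are ordered by `q_bh`, then `hmp`, then
#' `pathway_id`.
#'
#' @param surviving data.frame from [prune_pathways()].
#' @param db a [pathway_db] (display names).
#' @return `vote_table` data.frame with columns `pathway_id`, `name`,
#'   `votes`, `hmp`, `calibrated_p`, `q_bh`, `n_union_genes`, `union_genes`
#'   (semicolon-joined) and list columns `member_pvalues`, `gene_hit_list`.
#' @export
aggregate_votes <- function(surviving, db = NULL) {
  if (!nrow(surviving)) {
    out <- data.frame(pathway_id = character(0), name = character(0),
                      votes = integer(0), hmp = numeric(0),
                      calibrated_p = numeric(0), q_bh = numeric(0),
                      n_union_genes = integer(0), union_genes = character(0))
    out$member_pvalues <- list()
    out$gene_hit_list <- list()
    class(out) <- c("vote_table", "data.frame")
    return(out)
  }
  ids <- sort(unique(surviving$pathway_id))
  rows <- lapply(ids, function(id) {
    rec <- surviving[surviving$pathway_id == id, , drop = FALSE]
    rec <- rec[order(rec$run_id), , drop = FALSE]  # input order must not matter
    votes <- nrow(rec)
    h <- harmonic_mean_p(rec$p_raw)
    un <- sort(unique(unlist(rec$gene_hits, use.names = FALSE)))
    list(id = id, votes = votes, hmp = h,
         cal = calibrate_hmp(h, votes), union = un, pvals = rec$p_raw)
  })
  out <- data.frame(
    pathway_id = ids,
    name = if (is.null(db)) ids else unname(db$pathway_names[ids]),
    votes = vapply(rows, `[[`, 0L, "votes"),
    hmp = vapply(rows, `[[`, 0, "hmp"),
    calibrated_p = vapply(rows, `[[`, 0, "cal"),
    stringsAsFactors = FALSE)
  out$q_bh <- stats::p.adjust(out$calibrated_p, method = "BH")
  out$n_union_genes <- vapply(rows, function(r) length(r$union), 0L)
  out$union_genes <- vapply(rows, function(r) paste(r$union, collapse = ";"), "")
  out$member_pvalues <- lapply(rows, `[[`, "pvals")
  out$gene_hit_list <- lapply(rows, `[[`, "union")
  out <- out[order(out$q_bh, out$hmp, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vote_table", "data.frame")
  out
}
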