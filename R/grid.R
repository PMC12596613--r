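#' Number of FDR-significant CpGs
#'
#' Benjamini-Hochberg adjusts the EWAS p-values (over all CpGs in the table)
#' and counts CpGs with adjusted p strictly below `alpha`. This count anchors
#' the upper end of the top-k grid.
#'
#' @param ewas an [ewas_results] object with `metric_kind = "pvalue"`.
#' @param alpha FDR level (default 0.05).
#' @return integer count.
#' @export
count_fdr_significant <- function(ewas, alpha = 0.05) {
  stopifnot(inherits(ewas, "ewas_results"))
  if (ewas$metric_kind != "pvalue")
    stopf("FDR-based k selection needs p-values; supply k_values explicitly for metric_kind '%s'",
          ewas$metric_kind)
  sum(stats::p.adjust(ewas$data$metric, method = "BH") < alpha)
}

#' Log-spaced top-k values
#'
#' `n_points` k values on a natural-log scale between 25% and 100% of
#' `n_sig`, rounded and de-duplicated; sampling is denser at small k. The
#' largest value always equals `n_sig`; a single point returns the upper
#' bound.
#'
#' @param n_sig anchor count (e.g. number of FDR-significant CpGs); must be
#'   at least 4 so that the 25% lower end is at least 1.
#' @param n_points number of grid points before de-duplication.
#' @return increasing integer vector.
#' @export
make_k_values <- function(n_sig, n_points) {
  if (!is_count(n_points)) stopf("n_points must be a positive integer")
  if (!is_count(n_sig, min = 0L) || n_sig < 4)
    stopf("too few ranked CpGs to anchor the k grid (n_sig = %s < 4); supply k_values explicitly",
          format(n_sig))
  if (n_points == 1L) return(as.integer(n_sig))
  k <- round(exp(seq(log(0.25 * n_sig), log(n_sig), length.out = n_points)))
  k[n_points] <- n_sig
  sort(unique(as.integer(k)))
}

#' Evenly spaced threshold grid between two percentiles
#'
#' `n_points` values evenly spaced (in value space) between the `lo_pct`-th
#' and `hi_pct`-th percentiles of the observed distribution
#' (linear-interpolation percentile definition). A single point returns the
#' lower end of the band; a degenerate (constant) distribution collapses to
#' one value.
#'
#' @param values numeric observations (e.g. absolute eQTM effect sizes, or
#'   CpG-TSS distances).
#' @param n_points number of grid points.
#' @param lo_pct,hi_pct percentile band (defaults 5 and 95).
#' @return numeric vector (ascending, de-duplicated).
#' @export
make_threshold_grid <- function(values, n_points, lo_pct = 5, hi_pct = 95) {
  if (!length(values) || anyNA(values)) stopf("values must be non-empty without NA")
  if (!is_count(n_points)) stopf("n_points must be a positive integer")
  q <- stats::quantile(values, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  unique(seq(q[1], q[2], length.out = n_points))
}

#' Build the (k, e, d) parameter grid
#'
#' k values come from [make_k_values()] on the FDR-significant CpG count
#' (or from `k_values` when the ranking metric is not a p-value); effect
#' thresholds from the 5th-95th percentile band of the absolute eQTM effect
#' sizes; distance thresholds from the same band of the CpG-TSS distances.
#' Single-point effect/distance grids take the least stringent end of their
#' band (low for effect, high for distance).
#'
#' @param ewas an [ewas_results] object.
#' @param eqtm an `eqtm` resource.
#' @param n_k,n_e,n_d grid densities (defaults 5, giving at most 125 cells).
#' @param k_values optional explicit top-k values (required for
#'   non-p-value metrics); overrides the FDR rule.
#' @param alpha FDR level for the k anchor.
#' @return Object of class `parameter_grid`: list with `k_values`,
#'   `e_thresholds`, `d_thresholds`.
#' @export
build_grid <- function(ewas, eqtm, n_k = 5, n_e = 5, n_d = 5, k_values = NULL,
                       alpha = 0.05) {
  stopifnot(inherits(ewas, "ewas_results"), inherits(eqtm, "eqtm"))
  if (is.null(k_values)) {
    k_values <- make_k_values(count_fdr_significant(ewas, alpha), n_k)
  } else {
    k_values <- sort(unique(as.integer(k_values)))
    if (!length(k_values) || any(k_values < 1)) stopf("k_values must be positive integers")
  }
  if (max(k_values) > nrow(ewas$data))
    stopf("largest k (%d) exceeds the number of ranked CpGs (%d)",
          max(k_values), nrow(ewas$data))
  e_thr <- make_threshold_grid(abs(eqtm$pairs$effect), n_e)
  d_thr <- if (n_d == 1L)
    make_threshold_grid(eqtm$pairs$distance, 1L, lo_pct = 95, hi_pct = 95)
  else make_threshold_grid(eqtm$pairs$distance, n_d)
  structure(list(k_values = k_values, e_thresholds = e_thr, d_thresholds = d_thr),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("parameter_grid: %d k x %d e x %d d = %d cells\n",
              length(x$k_values), length(x$e_thresholds), length(x$d_thresholds),
              length(x$k_values) * length(x$e_thresholds) * length(x$d_thresholds)))
  cat("  k:", paste(x$k_values, collapse = ", "), "\n")
  cat("  e:", paste(signif(x$e_thresholds, 4), collapse = ", "), "\n")
  cat("  d:", paste(signif(x$d_thresholds, 4), collapse = ", "), "\n")
  invisible(x)
}

# Top-k CpG ids under the EWAS ranking; metric ties broken by cpg id so the
# selection is total and reproducible.
top_k_cpgs <- function(ewas, k) {
  d <- ewas$data
  if (k > nrow(d)) stopf("k (%d) exceeds number of CpGs (%d)", k, nrow(d))
  ord <- if (ewas$rank_direction == "smaller_better")
    order(d$metric, d$cpg) else order(-d$metric, d$cpg)
  d$cpg[ord[seq_len(k)]]
}

#' Materialize gene-list candidates over the grid
#'
#' For each top-k value, the top-k CpGs are selected under the EWAS ranking;
#' for each (e, d) cell the candidate gene list is the union of eQTM target
#' genes over links whose CpG is in the top-k set, with |effect| >= e and
#' distance <= d. Empty candidates are dropped, and exact-duplicate gene sets
#' within a k pool are collapsed to the least stringent cell (smallest e,
#' then largest d) before scoring, so pool sizes count distinct lists.
#'
#' @param ewas an [ewas_results] object.
#' @param eqtm an `eqtm` resource.
#' @param grid a `parameter_grid`.
#' @return named list (one element per k, name = k) of lists of candidates;
#'   each candidate is a list with `k`, `e_thr`, `d_thr`, `genes` (sorted),
#'   `cpgs_used`, and `ord` (grid enumeration order, e ascending then d
#'   ascending).
#' @export
generate_candidates <- function(ewas, eqtm, grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  pairs <- eqtm$pairs
  abs_eff <- abs(pairs$effect)
  out <- list()
  for (k in grid$k_values) {
    topk <- top_k_cpgs(ewas, k)
    in_top <- pairs$cpg %in% topk
    sub <- pairs[in_top, , drop = FALSE]
    sub_eff <- abs_eff[in_top]
    cands <- list()
    ord <- 0L
    for (e in grid$e_thresholds) {
      pass_e <- sub_eff >= e
      for (d in grid$d_thresholds) {
        ord <- ord + 1L
        sel <- pass_e & sub$distance <= d
        if (!any(sel)) next
        genes <- sort(unique(sub$gene[sel]))
        cands[[length(cands) + 1L]] <- list(
          k = as.integer(k), e_thr = e, d_thr = d, genes = genes,
          cpgs_used = sort(unique(sub$cpg[sel])), ord = ord)
      }
    }
    if (!length(cands)) next
    # collapse duplicate gene sets, keeping the least stringent cell
    keys <- vapply(cands, function(cc) paste(cc$genes, collapse = "\r"), "")
    keep <- integer(0)
    for (key in unique(keys)) {
      idx <- which(keys == key)
      if (length(idx) > 1L) {
        es <- vapply(cands[idx], `[[`, 0, "e_thr")
        ds <- vapply(cands[idx], `[[`, 0, "d_thr")
        idx <- idx[order(es, -ds)][1]
      }
      keep <- c(keep, idx)
    }
    out[[as.character(k)]] <- cands[sort(keep)]
  }
  out
}
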