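#' Build the candidate pool for one top-k value
#'
#' A pool gathers all gene-list candidates that share a top-k value, together
#' with per-gene recurrence counts n_k(g) (number of candidates containing
#' gene g) and CpG mapping density c(g) from the eQTM resource. Scoring and
#' pruning always operate within a single pool, never across k, so longer
#' lists from larger k cannot dominate.
#'
#' @param candidates list of candidates at one k (see [generate_candidates()]).
#' @param eqtm the `eqtm` resource (source of c(g)).
#' @return Object of class `candidate_pool`: list with `k`, `candidates`,
#'   `recurrence` (named integer), `cpg_density` (named integer).
#' @export
build_pool <- function(candidates, eqtm) {
  if (!length(candidates)) stopf("cannot build a pool from zero candidates")
  k <- candidates[[1]]$k
  genes <- unlist(lapply(candidates, `[[`, "genes"), use.names = FALSE)
  rec <- table(genes)
  recurrence <- stats::setNames(as.integer(rec), names(rec))
  dens <- eqtm$gene_counts[names(recurrence)]
  if (anyNA(dens))
    stopf("gene(s) in pool absent from eQTM resource: %s",
          paste(names(recurrence)[is.na(dens)][1], collapse = ", "))
  structure(list(k = k, candidates = candidates, recurrence = recurrence,
                 cpg_density = stats::setNames(as.integer(dens), names(recurrence))),
            class = "candidate_pool")
}

#' Information score of a candidate gene list
#'
#' Average self-information of the member genes relative to their recurrence
#' frequency across the pool, with Laplace smoothing:
#' I(G) = mean over g in G of -ln((n_k(g) + alpha) / (N_k + 2 alpha)).
#' Lists enriched for genes that are rare across candidates score higher.
#'
#' @param genes character vector of member genes (non-empty).
#' @param pool a `candidate_pool`.
#' @param alpha Laplace smoothing constant (default 1).
#' @return positive scalar.
#' @export
information_score <- function(genes, pool, alpha = 1) {
  if (!length(genes)) stopf("information score of an empty gene list is undefined")
  n <- pool$recurrence[genes]
  if (anyNA(n)) stopf("gene(s) not present in pool recurrence table")
  N <- length(pool$candidates)
  mean(-log((n + alpha) / (N + 2 * alpha)))
}

#' Jaccard similarity of two gene sets
#'
#' |A intersect B| / |A union B|; two empty sets are defined to have
#' similarity 0 so the function is total.
#'
#' @param a,b character vectors (sets).
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Discordance penalty of a candidate within its pool
#'
#' Mean Jaccard distance (1 - J) from the candidate to the other N_k - 1
#' candidates in the pool. Single-candidate pools have no comparators and
#' return 0.
#'
#' @param index position of the candidate in `pool$candidates`.
#' @param pool a `candidate_pool`.
#' @return scalar in `[0, 1]`.
#' @export
discordance_penalty <- function(index, pool) {
  N <- length(pool$candidates)
  if (N < 2L) return(0)
  g <- pool$candidates[[index]]$genes
  others <- pool$candidates[-index]
  mean(vapply(others, function(cc) 1 - jaccard(g, cc$genes), 0))
}

#' Fit the CpG-density over-representation model for a pool
#'
#' Genes that many CpGs map to recur across candidates for mapping-density
#' reasons alone. The expected recurrence is modelled by a quasi-Poisson GLM
#' with natural-log link, one observation per distinct gene in the pool:
#' response n_k(g), covariate x(g) = ln(1 + c(g)). Point estimates coincide
#' with Poisson maximum likelihood (the dispersion does not affect fitted
#' means, which are all that enter the penalty). Pools with fewer than two
#' distinct covariate values get an intercept-only fit.
#'
#' @param pool a `candidate_pool`.
#' @return list with `beta0`, `beta1`, `fitted` (named, positive expected
#'   recurrence per gene).
#' @export
fit_overrepresentation_glm <- function(pool) {
  y <- as.numeric(pool$recurrence)
  x <- log(1 + as.numeric(pool$cpg_density))
  genes <- names(pool$recurrence)
  if (length(unique(x)) < 2L) {
    m <- mean(y)
    return(list(beta0 = log(m), beta1 = 0,
                fitted = stats::setNames(rep(m, length(y)), genes)))
  }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::quasipoisson()))
  if (!fit$converged)
    stopf("over-representation GLM did not converge (pool k = %d, %d genes)",
          pool$k, length(y))
  co <- stats::coef(fit)
  list(beta0 = unname(co[1]), beta1 = unname(co[2]),
       fitted = stats::setNames(as.numeric(stats::fitted(fit)), genes))
}

#' Over-representation penalty of a candidate
#'
#' Only recurrence in excess of the CpG-density expectation is penalized:
#' R(G) = sum over g in G of ln(1 + max(0, n_k(g) - nhat_k(g))). The log
#' keeps extreme residuals from dominating; genes at or below expectation
#' contribute nothing.
#'
#' @param genes character vector of member genes.
#' @param fit result of [fit_overrepresentation_glm()].
#' @param pool the `candidate_pool`.
#' @return non-negative scalar.
#' @export
overrepresentation_penalty <- function(genes, fit, pool) {
  n <- as.numeric(pool$recurrence[genes])
  nhat <- as.numeric(fit$fitted[genes])
  if (anyNA(nhat)) stopf("GLM fit does not cover all candidate genes")
  sum(log(1 + pmax(0, n - nhat)))
}

#' Composite pruning scores for a pool
#'
#' Computes I, D, R for every candidate, z-scores each component within the
#' pool (population standard deviation; a zero-variance component contributes
#' zero), and combines them as S = zI - zD - zR.
#'
#' @param pool a `candidate_pool`.
#' @return data.frame with one row per candidate: `e_thr`, `d_thr`,
#'   `n_genes`, `I`, `D`, `R`, `zI`, `zD`, `zR`, `S`.
#' @export
composite_scores <- function(pool) {
  fit <- fit_overrepresentation_glm(pool)
  I <- vapply(pool$candidates, function(cc) information_score(cc$genes, pool), 0)
  D <- vapply(seq_along(pool$candidates), discordance_penalty, 0, pool = pool)
  R <- vapply(pool$candidates, function(cc)
    overrepresentation_penalty(cc$genes, fit, pool), 0)
  zI <- zscore_pop(I); zD <- zscore_pop(D); zR <- zscore_pop(R)
  data.frame(
    e_thr = vapply(pool$candidates, `[[`, 0, "e_thr"),
    d_thr = vapply(pool$candidates, `[[`, 0, "d_thr"),
    n_genes = vapply(pool$candidates, function(cc) length(cc$genes), 0L),
    I = I, D = D, R = R, zI = zI, zD = zD, zR = zR, S = zI - zD - zR)
}

#' Greedy non-redundant candidate selection
#'
#' Iteratively retains the remaining candidate with the highest composite
#' score (ties: larger gene list, then grid enumeration order) and removes
#' all remaining candidates whose Jaccard similarity with the retained list
#' exceeds the threshold (strictly above; similarity exactly at the threshold
#' is kept). Repeats until the pool is exhausted.
#'
#' @param pool a `candidate_pool`.
#' @param scores result of [composite_scores()] for the pool (recomputed when
#'   omitted).
#' @param jaccard_threshold overlap threshold (default 0.7).
#' @return list of retained candidates, in pick order.
#' @export
prune_pool <- function(pool, scores = NULL, jaccard_threshold = 0.7) {
  if (is.null(scores)) scores <- composite_scores(pool)
  ordv <- vapply(pool$candidates, `[[`, 0L, "ord")
  pref <- order(-scores$S, -scores$n_genes, ordv)
  remaining <- pref
  picked <- integer(0)
  while (length(remaining)) {
    top <- remaining[1]
    picked <- c(picked, top)
    g <- pool$candidates[[top]]$genes
    remaining <- remaining[-1]
    if (length(remaining)) {
      J <- vapply(remaining, function(i) jaccard(g, pool$candidates[[i]]$genes), 0)
      remaining <- remaining[J <= jaccard_threshold]
    }
  }
  pool$candidates[picked]
}

#' Prune all k pools independently
#'
#' @param pools named list of `candidate_pool` objects (one per k).
#' @param jaccard_threshold overlap threshold (default 0.7).
#' @return named list (per k) of retained candidate lists, in pick order.
#' @export
prune_all <- function(pools, jaccard_threshold = 0.7) {
  lapply(pools, function(pool)
    prune_pool(pool, jaccard_threshold = jaccard_threshold))
}
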