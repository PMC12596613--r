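# Fixture builders and independent oracles shared across test files.

toy_eqtm_table <- function() {
  data.frame(
    cpg = c("c1", "c1", "c2", "c2", "c3"),
    gene = c("G1", "G2", "G1", "G3", "G2"),
    effect = c(0.6, 0.2, -0.5, 0.3, 0.4),
    distance = c(100, 5000, 200, 800, 1500),
    pair_pvalue = c(1e-9, 1e-3, 1e-8, 1e-4, 1e-6),
    stringsAsFactors = FALSE)
}

make_grid <- function(k, e, d) {
  structure(list(k_values = as.integer(k), e_thresholds = e, d_thresholds = d),
            class = "parameter_grid")
}

make_candidate <- function(genes, k = 1L, e_thr = 0, d_thr = Inf, ord = 1L) {
  list(k = as.integer(k), e_thr = e_thr, d_thr = d_thr,
       genes = sort(genes), cpgs_used = character(0), ord = as.integer(ord))
}

# eQTM resource in which gene g has exactly counts[g] distinct CpGs
eqtm_with_counts <- function(counts) {
  rows <- do.call(rbind, lapply(names(counts), function(g)
    data.frame(cpg = sprintf("%s_cpg%d", g, seq_len(counts[[g]])), gene = g,
               effect = 0.5, distance = 100, pair_pvalue = 1e-8,
               stringsAsFactors = FALSE)))
  create_eqtm(rows, id_normalizer = identity)
}

make_pool <- function(gene_lists, cpg_counts = NULL) {
  cands <- lapply(seq_along(gene_lists), function(i)
    make_candidate(gene_lists[[i]], ord = i))
  genes <- unique(unlist(gene_lists))
  if (is.null(cpg_counts)) cpg_counts <- stats::setNames(rep(1L, length(genes)), genes)
  build_pool(cands, eqtm_with_counts(as.list(cpg_counts)))
}

# Poisson log-link GLM by hand-rolled iteratively reweighted least squares;
# independent of stats::glm.
irls_poisson <- function(y, x, tol = 1e-12, maxit = 200) {
  X <- cbind(1, x)
  beta <- c(log(mean(y) + 0.1), 0)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    W <- mu
    beta_new <- solve(t(X) %*% (W * X), t(X) %*% (W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(beta0 = beta[1], beta1 = beta[2], fitted = exp(drop(X %*% beta)))
}

# Exhaustive hypergeometric upper tail via the combinatorial sum.
hyper_tail_enum <- function(x, list_n, path_K, universe_N) {
  js <- x:min(list_n, path_K)
  sum(choose(path_K, js) * choose(universe_N - path_K, list_n - js)) /
    choose(universe_N, list_n)
}

# Per-row scan oracle for candidate gene lists at one grid cell.
brute_candidate_genes <- function(ewas, eqtm, k, e_thr, d_thr) {
  topk <- pathwayvote:::top_k_cpgs(ewas, k)
  genes <- character(0)
  for (i in seq_len(nrow(eqtm$pairs))) {
    row <- eqtm$pairs[i, ]
    if (row$cpg %in% topk && abs(row$effect) >= e_thr && row$distance <= d_thr)
      genes <- c(genes, row$gene)
  }
  sort(unique(genes))
}

small_cfg <- function(...) {
  simulation_config(n_noise_cpgs = 4000, n_reps = 2, seed = 99,
                    n_genes = 1200, min_pathway_genes = 60,
                    max_pathway_genes = 100, n_background_pathways = 15,
                    genes_per_pathway = 12, ...)
}
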