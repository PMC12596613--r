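#' Simulation study configuration
#'
#' Study conditions for the synthetic benchmark: 7 signal pathways drawn from
#' 14 top-level pathways of at least 200 genes and pairwise Jaccard below
#' 0.2; 25 signal genes per pathway with up to 3 strongly linked CpGs each
#' (eQTM pair p-value below 1e-7); signal CpG effect scores Normal(3, 0.5)
#' against Normal(0, 1) noise scores on 100,000 noise CpGs; 1000 replicates.
#' Generator shape parameters (gene pool size, CpG density distribution,
#' eQTM effect/distance distributions) are documented in the methods
#' vignette.
#'
#' @param n_signal_pathways signal pathways per replicate (default 7).
#' @param n_top_level top-level pathways in the universe (default 14).
#' @param min_pathway_genes,max_pathway_genes top-level size range
#'   (defaults 200 and 350).
#' @param max_pairwise_jaccard redundancy cap among top-level pathways
#'   (default 0.2).
#' @param genes_per_pathway signal genes sampled per signal pathway
#'   (default 25).
#' @param max_cpgs_per_gene strong CpGs selected per signal gene (default 3).
#' @param strong_eqtm_p eQTM pair p-value cutoff defining a strong link
#'   (default 1e-7).
#' @param n_noise_cpgs noise CpGs per replicate (default 100000).
#' @param signal_effect_mean,signal_effect_sd signal score distribution
#'   (defaults 3 and 0.5).
#' @param noise_effect_mean,noise_effect_sd noise score distribution
#'   (defaults 0 and 1).
#' @param n_reps replicates (default 1000).
#' @param seed master seed.
#' @param n_genes gene pool size (default 6000).
#' @param n_background_pathways non-hierarchy background pathways
#'   (default 60).
#' @param eqtm_sample_size nominal eQTM study sample size converting
#'   correlation magnitude to pair p-value (default 1000).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_signal_pathways = 7, n_top_level = 14,
                              min_pathway_genes = 200, max_pathway_genes = 350,
                              max_pairwise_jaccard = 0.2, genes_per_pathway = 25,
                              max_cpgs_per_gene = 3, strong_eqtm_p = 1e-7,
                              n_noise_cpgs = 100000, signal_effect_mean = 3,
                              signal_effect_sd = 0.5, noise_effect_mean = 0,
                              noise_effect_sd = 1, n_reps = 1000, seed = 1,
                              n_genes = 6000, n_background_pathways = 60,
                              eqtm_sample_size = 1000) {
  cfg <- as.list(environment())
  if (cfg$n_signal_pathways > cfg$n_top_level)
    stopf("n_signal_pathways must not exceed n_top_level")
  if (cfg$signal_effect_sd <= 0 || cfg$noise_effect_sd <= 0)
    stopf("effect score standard deviations must be positive")
  if (cfg$min_pathway_genes > cfg$max_pathway_genes)
    stopf("min_pathway_genes exceeds max_pathway_genes")
  if (cfg$n_genes < 2 * cfg$max_pathway_genes)
    stopf("gene pool too small for the requested pathway sizes")
  structure(cfg, class = "simulation_config")
}

max_pairwise_jaccard_of <- function(sets) {
  n <- length(sets)
  if (n < 2) return(0)
  m <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    m <- max(m, jaccard(sets[[i]], sets[[j]]))
  m
}

#' Generate a synthetic eQTM / pathway universe
#'
#' Builds a pathway database with `n_top_level` low-redundancy top-level
#' pathways, 2-5 direct descendants per top-level pathway (proper subsets of
#' the parent, 20-50% of its size), and background pathways; an eQTM
#' resource with right-skewed per-gene CpG counts, many-to-many CpG-gene
#' links, correlation-style effect sizes in (-1, 1), CpG-TSS distances up to
#' 1 Mb, and pair p-values spanning strong and weak links; a nearest-gene
#' style annotation assigning each mapped CpG its single strongest-effect
#' gene; and enough additional unmapped CpGs that noise CpGs can be drawn.
#' Deterministic given the seed.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed.
#' @return Object of class `synthetic_universe`: list with `db`, `eqtm`,
#'   `annotation`, `all_cpgs`, `strong_by_gene`, `cfg`, `seed`.
#' @export
generate_universe <- function(cfg, seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))

    # top-level pathways: retry until the redundancy constraint holds
    top_ids <- sprintf("TL%02d", seq_len(cfg$n_top_level))
    for (attempt in 1:25) {
      top_sets <- lapply(seq_len(cfg$n_top_level), function(i)
        sort(sample(genes, sample(cfg$min_pathway_genes:cfg$max_pathway_genes, 1))))
      if (max_pairwise_jaccard_of(top_sets) < cfg$max_pairwise_jaccard) break
      if (attempt == 25)
        stopf("could not satisfy the pairwise Jaccard < %g constraint; enlarge n_genes",
              cfg$max_pairwise_jaccard)
    }
    names(top_sets) <- top_ids

    # direct descendants: proper subsets, 20-50% of the parent
    child_sets <- list(); edges <- NULL
    for (tid in top_ids) {
      nc <- sample(2:5, 1)
      for (j in seq_len(nc)) {
        cid <- sprintf("%s.C%d", tid, j)
        sz <- max(2L, round(stats::runif(1, 0.2, 0.5) * length(top_sets[[tid]])))
        child_sets[[cid]] <- sort(sample(top_sets[[tid]], sz))
        edges <- rbind(edges, data.frame(parent = tid, child = cid,
                                         stringsAsFactors = FALSE))
      }
    }

    bg_sets <- lapply(seq_len(cfg$n_background_pathways), function(i)
      sort(sample(genes, sample(20:200, 1))))
    names(bg_sets) <- sprintf("BG%03d", seq_len(cfg$n_background_pathways))

    db <- pathway_db(c(top_sets, child_sets, bg_sets), hierarchy = edges,
                     top_level = top_ids, id_normalizer = identity)

    # eQTM with a host/distal link structure. Each CpG is hosted near one
    # gene (proximal link, short TSS distance, stronger correlation on
    # average); a gene's remaining links are distal, attaching to CpGs
    # hosted by other genes (long distance, weaker but frequently still
    # statistically strong correlation). This reproduces the many-to-many
    # structure and the partial discordance between position-style
    # annotation and regulatory targets seen in real eQTM resources.
    # Per-gene link counts c(g) are right-skewed (log-normal Poisson
    # mixture, capped at 30).
    lam <- stats::rlnorm(cfg$n_genes, meanlog = 0.55, sdlog = 0.9)
    cg <- pmin(1L + stats::rpois(cfg$n_genes, lam), 30L)
    # regulation mode is a gene property: promoter-driven genes carry their
    # strong links proximally; enhancer-driven genes are reached mostly
    # through distal CpGs hosted near other genes
    enhancer_driven <- stats::runif(cfg$n_genes) < 0.5
    link_gene <- rep(genes, cg)
    link_enh <- rep(enhancer_driven, cg)
    L <- length(link_gene)
    proximal <- stats::runif(L) < ifelse(link_enh, 0.15, 0.85)
    proximal[!duplicated(link_gene)] <- TRUE  # every gene hosts >= 1 CpG
    prox_ids <- sprintf("cg%07d", seq_len(sum(proximal)))
    link_cpg <- character(L)
    link_cpg[proximal] <- prox_ids
    link_cpg[!proximal] <- sample(prox_ids, sum(!proximal), replace = TRUE)
    # correlation magnitudes by gene mode and link type: a mode's preferred
    # route carries the stronger correlations
    mag <- numeric(L)
    sel <- proximal & !link_enh
    mag[sel] <- 0.9 * stats::rbeta(sum(sel), 2.5, 4)
    sel <- proximal & link_enh
    mag[sel] <- 0.9 * stats::rbeta(sum(sel), 1.5, 8)
    sel <- !proximal & !link_enh
    mag[sel] <- 0.9 * stats::rbeta(sum(sel), 2, 6)
    sel <- !proximal & link_enh
    mag[sel] <- 0.9 * stats::rbeta(sum(sel), 2.5, 5)
    effect <- sample(c(-1, 1), L, replace = TRUE) * mag
    pair_p <- pmin(1, pmax(2 * stats::pnorm(mag * sqrt(cfg$eqtm_sample_size),
                                            lower.tail = FALSE), 1e-300))
    distance <- ifelse(proximal, abs(stats::rnorm(L, 0, 20000)),
                       stats::runif(L, 5e3, 1e6))
    distance <- pmin(distance, 1e6)
    eqtm <- create_eqtm(data.frame(cpg = link_cpg, gene = link_gene,
                                   effect = effect, distance = distance,
                                   pair_pvalue = pair_p, stringsAsFactors = FALSE),
                        id_normalizer = identity)

    # nearest-gene style annotation: single strongest-effect gene per CpG
    pr <- eqtm$pairs[order(eqtm$pairs$cpg, -abs(eqtm$pairs$effect)), ]
    first <- !duplicated(pr$cpg)
    annotation <- stats::setNames(pr$gene[first], pr$cpg[first])

    strong <- eqtm$pairs[eqtm$pairs$pair_pvalue < cfg$strong_eqtm_p, ]
    strong_by_gene <- split(strong$cpg, strong$gene)

    mapped <- unique(eqtm$pairs$cpg)
    n_extra <- max(0L, as.integer(cfg$n_noise_cpgs + 3000 - length(mapped)))
    all_cpgs <- c(mapped, if (n_extra) sprintf("ncg%07d", seq_len(n_extra)))

    structure(list(db = db, eqtm = eqtm, annotation = annotation,
                   all_cpgs = all_cpgs, strong_by_gene = strong_by_gene,
                   cfg = cfg, seed = seed),
              class = "synthetic_universe")
  })
}

#' @export
print.synthetic_universe <- function(x, ...) {
  cat(sprintf(paste0("synthetic_universe: %d pathways (%d top-level), ",
                     "%d eQTM pairs, %d CpGs total\n"),
              length(x$db$genesets), length(x$db$top_level),
              nrow(x$eqtm$pairs), length(x$all_cpgs)))
  invisible(x)
}

#' Simulate one replicate's EWAS results
#'
#' Samples the signal pathways and signal genes, selects up to
#' `max_cpgs_per_gene` strongly eQTM-linked CpGs per signal gene (genes with
#' no strong link contribute none), draws signal scores Normal(mean, sd) and
#' noise scores for `n_noise_cpgs` CpGs drawn from the non-signal CpG pool,
#' and converts scores to one-sided upper-tail normal p-values (stronger
#' association, smaller p).
#'
#' @param universe a `synthetic_universe`.
#' @param cfg a [simulation_config()].
#' @param rep_seed integer seed for this replicate.
#' @return list with `ewas` ([ewas_results], p-value metric) and `truth`
#'   (list: `pathways`, `genes`, `cpgs`).
#' @export
simulate_ewas <- function(universe, cfg, rep_seed) {
  stopifnot(inherits(universe, "synthetic_universe"))
  with_seed(rep_seed, {
    signal_paths <- sample(universe$db$top_level, cfg$n_signal_pathways)
    signal_genes <- unlist(lapply(signal_paths, function(p) {
      gs <- universe$db$genesets[[p]]
      sample(gs, min(cfg$genes_per_pathway, length(gs)))
    }), use.names = FALSE)
    signal_genes <- unique(signal_genes)
    signal_cpgs <- unique(unlist(lapply(signal_genes, function(g) {
      sc <- universe$strong_by_gene[[g]]
      if (is.null(sc)) return(character(0))  # no strong eQTM evidence
      sc <- unique(sc)
      if (length(sc) > cfg$max_cpgs_per_gene)
        sc <- sc[sample.int(length(sc), cfg$max_cpgs_per_gene)]
      sc
    }), use.names = FALSE))
    noise_pool <- setdiff(universe$all_cpgs, signal_cpgs)
    if (length(noise_pool) < cfg$n_noise_cpgs)
      stopf("universe has too few non-signal CpGs (%d < %d)",
            length(noise_pool), cfg$n_noise_cpgs)
    noise_cpgs <- sample(noise_pool, cfg$n_noise_cpgs)
    scores <- c(stats::rnorm(length(signal_cpgs), cfg$signal_effect_mean,
                             cfg$signal_effect_sd),
                stats::rnorm(length(noise_cpgs), cfg$noise_effect_mean,
                             cfg$noise_effect_sd))
    pvals <- pmax(stats::pnorm(scores, lower.tail = FALSE), 1e-300)
    list(ewas = ewas_results(c(signal_cpgs, noise_cpgs), pvals, "pvalue"),
         truth = list(pathways = signal_paths, genes = sort(signal_genes),
                      cpgs = signal_cpgs))
  })
}

#' Score one replicate against the planted truth
#'
#' Detection set: pathways with `q_bh < q_cutoff`. A planted top-level
#' pathway counts as recovered when it or any of its direct descendants is
#' detected (the hierarchy-aware success rule); a non-signal top-level
#' family counts as a false positive under the same rule. Signal-gene
#' coverage is the fraction of planted signal genes contained in the union
#' of detected pathways' member gene sets.
#'
#' @param result a vote table or baseline result (needs `pathway_id`,
#'   `q_bh`).
#' @param truth truth list from [simulate_ewas()].
#' @param db the universe's [pathway_db].
#' @param q_cutoff detection cutoff (default 0.05).
#' @return list of class `run_metrics`: `sensitivity`, `specificity`,
#'   `signal_gene_coverage`, `mean_detected_pathway_size` (NA when nothing
#'   is detected), `n_detected`, `detected_per_truth`.
#' @export
score_run <- function(result, truth, db, q_cutoff = 0.05) {
  detected <- if (nrow(result)) result$pathway_id[result$q_bh < q_cutoff]
  else character(0)
  fam <- function(p) c(p, db$hierarchy$child[db$hierarchy$parent == p])
  hit <- function(p) any(fam(p) %in% detected)
  recovered <- vapply(truth$pathways, hit, TRUE)
  nonsignal <- setdiff(db$top_level, truth$pathways)
  fp <- if (length(nonsignal)) vapply(nonsignal, hit, TRUE) else logical(0)
  detected_genes <- unique(unlist(db$genesets[detected], use.names = FALSE))
  structure(list(
    sensitivity = mean(recovered),
    specificity = if (length(fp)) 1 - mean(fp) else 1,
    signal_gene_coverage =
      length(intersect(detected_genes, truth$genes)) / length(truth$genes),
    mean_detected_pathway_size =
      if (length(detected)) mean(lengths(db$genesets[detected])) else NA_real_,
    n_detected = length(detected),
    detected_per_truth = stats::setNames(recovered, truth$pathways)),
    class = "run_metrics")
}

#' Run the full simulation study
#'
#' Generates (or reuses) a synthetic universe, then for each replicate
#' simulates EWAS results and runs the requested methods on the same data
#' (paired design): the consensus voting pipeline and/or the classical
#' nearest-gene baseline. Because the simulated ranking metric is an effect
#' score whose converted p-values sit at the Benjamini-Hochberg detection
#' boundary, the top-k anchor for both methods is the null-calibrated
#' non-null count from [estimate_signal_count()] (see the methods vignette);
#' replicates where that anchor is below 4 yield no detections for the
#' consensus method.
#'
#' @param cfg a [simulation_config()].
#' @param methods character subset of `c("pathwayvote", "classical")`.
#' @param n_k,n_e,n_d grid densities (defaults 4, the benchmark profile).
#' @param jaccard_threshold,min_votes,min_count,run_p_cutoff consensus
#'   pipeline settings (see [pathway_vote()]).
#' @param q_cutoff detection cutoff for both methods (default 0.05).
#' @param universe optional pre-built `synthetic_universe` (must match
#'   `cfg`).
#' @param verbose print per-replicate progress.
#' @return Object of class `simulation_study`: list with `summary`
#'   (per-method means and normal-approximation 95% CIs plus paired
#'   contrasts), `replicates` (long data.frame, one row per replicate and
#'   method), `detection` (per-top-level-pathway detection frequencies),
#'   `cfg`, `universe_seed`, `rep_seeds`.
#' @export
run_simulation_study <- function(cfg, methods = c("pathwayvote", "classical"),
                                 n_k = 4, n_e = 4, n_d = 4,
                                 jaccard_threshold = 0.7, min_votes = 2,
                                 min_count = 2, run_p_cutoff = 0.05, q_cutoff = 0.05,
                                 universe = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  methods <- match.arg(methods, c("pathwayvote", "classical"), several.ok = TRUE)
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, cfg$n_reps + 1L))
  universe_seed <- seeds[1]
  rep_seeds <- seeds[-1]
  if (is.null(universe)) universe <- generate_universe(cfg, universe_seed)

  rows <- vector("list", cfg$n_reps * length(methods))
  truth_count <- stats::setNames(integer(length(universe$db$top_level)),
                                 universe$db$top_level)
  det_count <- sapply(methods, function(m) truth_count, simplify = FALSE)
  ri <- 0L
  for (rep in seq_len(cfg$n_reps)) {
    sim <- simulate_ewas(universe, cfg, rep_seeds[rep])
    khat <- estimate_signal_count(sim$ewas)
    truth_count[sim$truth$pathways] <- truth_count[sim$truth$pathways] + 1L
    for (m in methods) {
      res <- if (m == "pathwayvote") {
        if (khat >= 4) {
          kv <- make_k_values(khat, n_k)
          pathway_vote(sim$ewas, universe$eqtm, universe$db, n_e = n_e,
                       n_d = n_d, k_values = kv,
                       jaccard_threshold = jaccard_threshold,
                       min_votes = min_votes, min_count = min_count,
                       run_p_cutoff = run_p_cutoff)$vote_table
        } else aggregate_votes(data.frame())
      } else {
        if (khat >= 1)
          classical_enrich(sim$ewas, universe$annotation, universe$db, k = khat)
        else classical_enrich(sim$ewas, universe$annotation, universe$db, k = 1)
      }
      sc <- score_run(res, sim$truth, universe$db, q_cutoff)
      det_count[[m]][names(sc$detected_per_truth)] <-
        det_count[[m]][names(sc$detected_per_truth)] + sc$detected_per_truth
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        rep = rep, method = m, sensitivity = sc$sensitivity,
        specificity = sc$specificity, coverage = sc$signal_gene_coverage,
        mean_pathway_size = sc$mean_detected_pathway_size,
        n_detected = sc$n_detected, k_anchor = khat,
        n_signal_cpgs = length(sim$truth$cpgs), stringsAsFactors = FALSE)
    }
    if (verbose && rep %% 10 == 0) message(sprintf("replicate %d/%d", rep, cfg$n_reps))
  }
  replicates <- do.call(rbind, rows)

  ci <- function(x) {
    x <- x[!is.na(x)]
    se <- stats::sd(x) / sqrt(length(x))
    c(mean = mean(x), lo = mean(x) - 1.96 * se, hi = mean(x) + 1.96 * se)
  }
  summary <- lapply(stats::setNames(methods, methods), function(m) {
    d <- replicates[replicates$method == m, ]
    list(sensitivity = ci(d$sensitivity), specificity = ci(d$specificity),
         coverage = ci(d$coverage),
         mean_pathway_size = ci(d$mean_pathway_size))
  })
  if (all(c("pathwayvote", "classical") %in% methods)) {
    pv <- replicates[replicates$method == "pathwayvote", ]
    cl <- replicates[replicates$method == "classical", ]
    summary$paired <- list(
      sensitivity_ratio = mean(pv$sensitivity) / mean(cl$sensitivity),
      coverage_ratio = mean(pv$coverage) / mean(cl$coverage),
      size_reduction_pct = 100 *
        (mean(cl$mean_pathway_size, na.rm = TRUE) -
           mean(pv$mean_pathway_size, na.rm = TRUE)) /
        mean(cl$mean_pathway_size, na.rm = TRUE),
      sensitivity_diff_mean = mean(pv$sensitivity - cl$sensitivity))
  }
  detection <- data.frame(pathway_id = universe$db$top_level,
                          times_truth = as.integer(truth_count),
                          stringsAsFactors = FALSE)
  for (m in methods)
    detection[[paste0("recovered_", m)]] <- as.integer(det_count[[m]])
  structure(list(summary = summary, replicates = replicates,
                 detection = detection, cfg = cfg,
                 universe_seed = universe_seed, rep_seeds = rep_seeds),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf("simulation_study: %d replicates\n", x$cfg$n_reps))
  for (m in setdiff(names(x$summary), "paired")) {
    s <- x$summary[[m]]
    cat(sprintf("  %-12s sens %.3f [%.3f, %.3f]  spec %.3f  cov %.3f  size %.1f\n",
                m, s$sensitivity["mean"], s$sensitivity["lo"], s$sensitivity["hi"],
                s$specificity["mean"], s$coverage["mean"],
                s$mean_pathway_size["mean"]))
  }
  if (!is.null(x$summary$paired))
    cat(sprintf("  paired: sens ratio %.2f, cov ratio %.2f, size reduction %.1f%%\n",
                x$summary$paired$sensitivity_ratio, x$summary$paired$coverage_ratio,
                x$summary$paired$size_reduction_pct))
  invisible(x)
}

#' Write simulation study outputs
#'
#' Writes `replicates.tsv` (one row per replicate and method),
#' `detection_frequency.tsv` (per-top-level-pathway recovery counts), and
#' `summary.json` into `dir`.
#'
#' @param study a `simulation_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(study$replicates, file.path(dir, "replicates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$detection, file.path(dir, "detection_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
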