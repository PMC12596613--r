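test_that("synthetic universes satisfy their structural constraints", {
  cfg <- small_cfg()
  uni <- generate_universe(cfg, 123)
  expect_identical(generate_universe(cfg, 123), uni)   # same seed, same universe

  top <- uni$db$genesets[uni$db$top_level]
  expect_length(top, cfg$n_top_level)
  expect_true(all(lengths(top) >= cfg$min_pathway_genes))
  expect_lt(pathwayvote:::max_pairwise_jaccard_of(top), cfg$max_pairwise_jaccard)

  # descendants are proper subsets of their parents, 2-5 per parent
  h <- uni$db$hierarchy
  kids_per_parent <- table(h$parent)
  expect_true(all(kids_per_parent >= 2 & kids_per_parent <= 5))
  for (i in seq_len(nrow(h))) {
    kid <- uni$db$genesets[[h$child[i]]]
    par <- uni$db$genesets[[h$parent[i]]]
    expect_true(all(kid %in% par) && length(kid) < length(par))
  }

  # every pathway gene is reachable through the eQTM; CpG pool large enough
  expect_true(all(unique(unlist(uni$db$genesets)) %in% uni$eqtm$pairs$gene))
  expect_gt(length(uni$all_cpgs),
            cfg$n_noise_cpgs + cfg$n_signal_pathways * cfg$genes_per_pathway *
              cfg$max_cpgs_per_gene)

  # eQTM shape: many-to-many, effects in (-1,1), distances within 1 Mb,
  # strong and weak pair p-values both present
  expect_gt(max(table(uni$eqtm$pairs$cpg)), 1)
  expect_true(all(abs(uni$eqtm$pairs$effect) < 1))
  expect_true(all(uni$eqtm$pairs$distance >= 0 & uni$eqtm$pairs$distance <= 1e6))
  expect_gt(sum(uni$eqtm$pairs$pair_pvalue < cfg$strong_eqtm_p), 0)
  expect_gt(sum(uni$eqtm$pairs$pair_pvalue > 0.01), 0)
})

test_that("simulated EWAS replicates obey the study conditions", {
  cfg <- small_cfg()
  uni <- generate_universe(cfg, 123)
  sim <- simulate_ewas(uni, cfg, 77)
  expect_identical(simulate_ewas(uni, cfg, 77), sim)

  expect_length(sim$truth$pathways, cfg$n_signal_pathways)
  expect_lte(length(sim$truth$cpgs),
             cfg$n_signal_pathways * cfg$genes_per_pathway * cfg$max_cpgs_per_gene)
  expect_equal(nrow(sim$ewas$data), length(sim$truth$cpgs) + cfg$n_noise_cpgs)

  # signal CpGs carry strong eQTM links by construction
  strong_cpgs <- unique(uni$eqtm$pairs$cpg[uni$eqtm$pairs$pair_pvalue < cfg$strong_eqtm_p])
  expect_true(all(sim$truth$cpgs %in% strong_cpgs))

  # mean signal score close to the configured mean (CLT bound)
  sig_scores <- qnorm(sim$ewas$data$metric[sim$ewas$data$cpg %in% sim$truth$cpgs],
                      lower.tail = FALSE)
  n_sig <- length(sig_scores)
  expect_lt(abs(mean(sig_scores) - cfg$signal_effect_mean),
            3 * cfg$signal_effect_sd / sqrt(n_sig))
})

test_that("run scoring applies the hierarchy-aware success rule", {
  cfg <- small_cfg()
  uni <- generate_universe(cfg, 123)
  db <- uni$db
  truth <- list(pathways = db$top_level[1:cfg$n_signal_pathways],
                genes = db$genesets[[db$top_level[1]]][1:10])
  as_result <- function(ids) data.frame(pathway_id = ids,
                                        q_bh = rep(0.001, length(ids)))

  perfect <- score_run(as_result(truth$pathways), truth, db)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$signal_gene_coverage, 1)

  # detecting only a direct descendant still recovers the family
  child1 <- db$hierarchy$child[db$hierarchy$parent == truth$pathways[1]][1]
  one <- score_run(as_result(child1), truth, db)
  expect_equal(one$sensitivity, 1 / cfg$n_signal_pathways)
  expect_true(one$detected_per_truth[[truth$pathways[1]]])

  # a non-signal family's descendant counts as a false positive
  other <- setdiff(db$top_level, truth$pathways)[1]
  childN <- db$hierarchy$child[db$hierarchy$parent == other][1]
  fp <- score_run(as_result(childN), truth, db)
  expect_equal(fp$specificity,
               1 - 1 / (cfg$n_top_level - cfg$n_signal_pathways))

  nothing <- score_run(as_result(character(0)), truth, db)
  expect_equal(nothing$sensitivity, 0)
  expect_equal(nothing$specificity, 1)
  expect_equal(nothing$signal_gene_coverage, 0)
  expect_true(is.na(nothing$mean_detected_pathway_size))

  # coverage is monotone in the detection set
  covs <- vapply(seq_along(db$top_level), function(m)
    score_run(as_result(db$top_level[1:m]), truth, db)$signal_gene_coverage, 0)
  expect_true(all(diff(covs) >= 0))
})

test_that("the study is paired, reproducible, and byte-stable on disk", {
  cfg <- small_cfg()
  st1 <- run_simulation_study(cfg, n_k = 3, n_e = 3, n_d = 3)
  st2 <- run_simulation_study(cfg, n_k = 3, n_e = 3, n_d = 3)
  expect_identical(st1$replicates, st2$replicates)

  # both methods score the same replicates (same seeds, same signal)
  pv <- st1$replicates[st1$replicates$method == "pathwayvote", ]
  cl <- st1$replicates[st1$replicates$method == "classical", ]
  expect_equal(pv$rep, cl$rep)
  expect_equal(pv$k_anchor, cl$k_anchor)
  expect_equal(pv$n_signal_cpgs, cl$n_signal_cpgs)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation_study(st1, d1)
  write_simulation_study(st2, d2)
  for (f in c("replicates.tsv", "detection_frequency.tsv", "summary.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_equal(sum(st1$detection$times_truth),
               cfg$n_reps * cfg$n_signal_pathways)
})

test_that("a signal-free study yields no top-k anchor", {
  set.seed(5)
  # pure-null scores: the non-null lower bound collapses to (near) zero
  p <- pnorm(rnorm(20000), lower.tail = FALSE)
  khat <- estimate_signal_count(p)
  expect_lt(khat, 4)
  expect_error(make_k_values(khat, 4), "k_values")

  # with signal present the anchor approaches the planted count
  p2 <- c(pnorm(rnorm(400, 3, 0.5), lower.tail = FALSE), p)
  khat2 <- estimate_signal_count(p2)
  expect_gt(khat2, 200)
  expect_lte(khat2, 500)
})
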