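test_that("hypergeometric upper tail matches hand enumeration", {
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10), 6 / 252, tolerance = 1e-9)
  expect_equal(hypergeom_upper_tail(0, 5, 4, 10), 1)
  expect_equal(hypergeom_upper_tail(1, 1, 3, 12), 3 / 12, tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(5, 4, 4, 10), "inconsistent")
  expect_error(hypergeom_upper_tail(2, 11, 4, 10), "inconsistent")
})

test_that("ORA restricts to the universe and reports overlapping pathways", {
  universe <- sprintf("g%d", 1:10)
  db <- pathway_db(list(P = sprintf("g%d", 1:4)), id_normalizer = identity)
  rec <- ora_enrich(c(sprintf("g%d", 1:4), "g9"), db, universe)
  expect_equal(rec$overlap_count, 4L)
  expect_equal(rec$p_raw, 6 / 252, tolerance = 1e-9)
  expect_setequal(rec$gene_hits[[1]], sprintf("g%d", 1:4))

  expect_equal(nrow(ora_enrich(c("g9", "g10"), db, universe)), 0L)

  # degenerate: pathway = universe = list
  db2 <- pathway_db(list(All = universe), id_normalizer = identity)
  rec2 <- ora_enrich(universe, db2, universe)
  expect_equal(rec2$p_raw, 1)

  expect_warning(ora_enrich("not_there", db, universe), "empty")
})

test_that("pathway pruning needs enough qualifying runs", {
  rec <- function(path, run, overlap, p = 1e-4)
    data.frame(pathway_id = path, run_id = run, p_raw = p,
               overlap_count = overlap, path_K = 10L, list_n = 10L,
               universe_N = 100L, gene_hits = I(list(letters[seq_len(overlap)])))
  records <- rbind(rec("A", "r1", 3), rec("A", "r2", 1), rec("A", "r3", 5),
                   rec("B", "r1", 4), rec("C", "r2", 2))
  out <- prune_pathways(records, min_votes = 2, min_count = 2, run_p_cutoff = 1)
  expect_setequal(out$pathway_id, "A")          # B and C appear once only
  expect_equal(nrow(out), 2L)                   # A's overlap-1 record dropped

  two <- rbind(rec("D", "r1", 2), rec("D", "r2", 2))
  expect_equal(nrow(prune_pathways(two, run_p_cutoff = 1)), 2L)
  expect_error(prune_pathways(two, min_votes = 1), "at least 2")
  expect_equal(nrow(prune_pathways(records[0, , drop = FALSE])), 0L)
})

test_that("run membership is gated on within-run adjusted significance", {
  rec <- function(path, run, p)
    data.frame(pathway_id = path, run_id = run, p_raw = p, overlap_count = 3L,
               path_K = 10L, list_n = 10L, universe_N = 100L,
               gene_hits = I(list(c("x", "y", "z"))))
  # run r1 tests two pathways: A at p = 0.001 (BH 0.002) and B at p = 0.9;
  # run r2 likewise; B never clears the within-run cutoff
  records <- rbind(rec("A", "r1", 0.001), rec("B", "r1", 0.9),
                   rec("A", "r2", 0.002), rec("B", "r2", 0.8))
  out <- prune_pathways(records, run_p_cutoff = 0.05)
  expect_setequal(out$pathway_id, "A")
  expect_equal(nrow(out), 2L)
  # disabling the gate restores both
  expect_setequal(prune_pathways(records, run_p_cutoff = 1)$pathway_id,
                  c("A", "B"))
})

test_that("harmonic mean p-value follows the weighted formula", {
  expect_equal(harmonic_mean_p(rep(0.037, 5)), 0.037, tolerance = 1e-12)
  expect_equal(harmonic_mean_p(c(0.01, 0.1)), 2 / 110, tolerance = 1e-12)
  expect_equal(harmonic_mean_p(c(0.01, 0.1), c(3, 1)), 4 / (300 + 10),
               tolerance = 1e-12)
  # harmonic mean never exceeds the arithmetic mean
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    expect_lte(harmonic_mean_p(p), mean(p))
  }
  expect_error(harmonic_mean_p(c(0.1, 0)), "\\(0,1\\]")
})

test_that("HMP calibration is identity at L=1, inflationary and monotone beyond", {
  expect_equal(calibrate_hmp(0.03, 1), 0.03)
  h <- 2 / 110
  cal <- calibrate_hmp(h, 2)
  expect_gte(cal, h)
  expect_lte(cal, 1)
  for (L in c(2, 5, 10)) {
    expect_gte(calibrate_hmp(0.2, L), 0.2)
    expect_lt(calibrate_hmp(0.001, L), calibrate_hmp(0.01, L))
    expect_lt(calibrate_hmp(0.01, L), calibrate_hmp(0.1, L))
  }
  expect_equal(calibrate_hmp(1, 3), 1, tolerance = 1e-6)
})

test_that("calibrated HMP keeps the null rejection rate at or below nominal", {
  # invert the calibration once, then check the empirical null tail
  L <- 5
  hstar <- uniroot(function(h) calibrate_hmp(h, L) - 0.05,
                   c(1e-4, 0.5), tol = 1e-10)$root
  set.seed(31)
  P <- matrix(runif(2e5 * L), ncol = L)
  frac <- mean(1 / rowMeans(1 / P) <= hstar)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 2e5))
})

test_that("vote aggregation combines, calibrates, adjusts, and orders", {
  rec <- function(path, run, p, hits)
    data.frame(pathway_id = path, run_id = run, p_raw = p,
               overlap_count = length(hits), path_K = 10L, list_n = 10L,
               universe_N = 100L, gene_hits = I(list(hits)))
  surv <- rbind(rec("P1", "r1", 0.01, c("a", "b")), rec("P1", "r2", 0.1, c("b", "c")))
  vt <- aggregate_votes(surv)
  expect_equal(vt$votes, 2L)
  expect_equal(vt$hmp, 2 / 110, tolerance = 1e-9)
  expect_equal(vt$q_bh, vt$calibrated_p)       # BH over one pathway is identity
  expect_equal(vt$union_genes, "a;b;c")
  expect_equal(vt$member_pvalues[[1]], c(0.01, 0.1))

  # permuting record order changes nothing
  surv3 <- rbind(surv, rec("P2", "r1", 0.2, c("d", "e")),
                 rec("P2", "r3", 0.4, c("d", "f")))
  vt_a <- aggregate_votes(surv3)
  vt_b <- aggregate_votes(surv3[sample(nrow(surv3)), , drop = FALSE])
  expect_equal(vt_a, vt_b)

  # a run in which a pathway does not appear never changes its hmp
  with_extra <- rbind(surv3, rec("P3", "r9", 0.5, c("z", "w")))
  vt_c <- aggregate_votes(with_extra)
  expect_equal(vt_c$hmp[vt_c$pathway_id == "P1"], vt_a$hmp[vt_a$pathway_id == "P1"])

  # q_bh is monotone along the calibrated_p ranking
  ord <- order(vt_c$calibrated_p)
  expect_true(all(diff(vt_c$q_bh[ord]) >= -1e-12))

  empty <- aggregate_votes(data.frame())
  expect_equal(nrow(empty), 0L)
  expect_s3_class(empty, "vote_table")
})
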