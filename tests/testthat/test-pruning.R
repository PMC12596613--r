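test_that("information score is the smoothed average self-information", {
  pool3 <- make_pool(list(c("g", "a"), c("a", "b"), c("a", "c")))
  # N_k = 3; g appears once
  expect_equal(information_score("g", pool3), -log(2 / 5), tolerance = 1e-12)
  expect_equal(information_score("a", pool3), -log(4 / 5), tolerance = 1e-12)
  pool1 <- make_pool(list("g"))
  expect_equal(information_score("g", pool1), -log(2 / 3), tolerance = 1e-12)
  expect_gt(information_score("g", pool3), 0)
  # strictly decreasing in the member's recurrence
  expect_gt(information_score("g", pool3), information_score("a", pool3))
  expect_error(information_score(character(0), pool3), "empty")
})

test_that("jaccard similarity handles the degenerate cases", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(character(0), character(0)), 0)
})

test_that("discordance averages Jaccard distance to the other candidates", {
  same <- make_pool(list(c("a", "b"), c("a", "b")))
  expect_equal(discordance_penalty(1, same), 0)
  disj <- make_pool(list(c("a", "b"), c("c", "d")))
  expect_equal(discordance_penalty(1, disj), 1)
  abc <- make_pool(list(c("a", "b"), c("b", "c"), c("a", "b")))
  expect_equal(discordance_penalty(1, abc), ((1 - 1 / 3) + 0) / 2, tolerance = 1e-12)
  expect_equal(discordance_penalty(1, make_pool(list("a"))), 0)  # N_k = 1
})

test_that("recurrence GLM matches closed forms and the IRLS oracle", {
  # one covariate level: intercept-only saturation
  flat <- make_pool(list(c("a", "b"), c("a", "b"), c("a", "b")),
                    cpg_counts = c(a = 2, b = 2))
  fit <- fit_overrepresentation_glm(flat)
  expect_equal(fit$beta1, 0)
  expect_equal(unname(fit$fitted), rep(3, 2))

  # two covariate levels: fitted means equal per-level sample means
  two <- make_pool(list(c("a", "b", "c"), c("a", "c"), c("a", "d")),
                   cpg_counts = c(a = 1, b = 1, c = 5, d = 5))
  fit2 <- fit_overrepresentation_glm(two)
  # level x = log(2): genes a (n=3), b (n=1) -> mean 2; level log(6): c (n=2), d (n=1) -> 1.5
  expect_equal(unname(fit2$fitted[c("a", "b")]), c(2, 2), tolerance = 1e-8)
  expect_equal(unname(fit2$fitted[c("c", "d")]), c(1.5, 1.5), tolerance = 1e-8)
  oracle <- irls_poisson(as.numeric(two$recurrence), log(1 + as.numeric(two$cpg_density)))
  expect_equal(unname(fit2$fitted), unname(oracle$fitted), tolerance = 1e-8)

  # response independent of covariate on a larger fixture: slope near zero
  set.seed(7)
  lists <- replicate(40, sample(letters, 8), simplify = FALSE)
  big <- make_pool(lists, cpg_counts = setNames(sample(1:20, 26, TRUE), letters))
  fit3 <- fit_overrepresentation_glm(big)
  expect_lt(abs(fit3$beta1), 0.5)
})

test_that("over-representation penalty clamps at the expectation", {
  pool <- make_pool(list(c("a", "b"), c("a", "b"), c("a", "c")),
                    cpg_counts = c(a = 3, b = 3, c = 3))
  fit <- list(beta0 = 0, beta1 = 0, fitted = c(a = 5, b = 5, c = 5))
  expect_equal(overrepresentation_penalty(c("a", "b"), fit, pool), 0)
  fit$fitted <- c(a = 3, b = 2, c = 1)
  # a: n=3, nhat=3 -> 0
  expect_equal(overrepresentation_penalty("a", fit, pool), 0)
  fit$fitted["a"] <- -2 + 3  # nhat = 1, excess 2
  expect_equal(overrepresentation_penalty("a", fit, pool), log(3), tolerance = 1e-12)
  # sublinear growth: doubling the excess adds less than log(2)
  expect_lt(log(3) - log(2), log(2))
})

test_that("composite scores are pool z-scores with S = zI - zD - zR", {
  single <- make_pool(list(c("a", "b")))
  sc1 <- composite_scores(single)
  expect_equal(sc1$S, 0)
  expect_equal(c(sc1$zI, sc1$zD, sc1$zR), c(0, 0, 0))

  # two candidates differing only in information: population z gives {-1, +1}
  # ({a} vs {a, b}: same discordance, same over-representation penalty)
  pool <- make_pool(list("a", c("a", "b")))
  sc <- composite_scores(pool)
  expect_equal(sc$zD, c(0, 0))
  expect_equal(sc$zR, c(0, 0))
  expect_equal(sc$S, c(-1, 1))

  # shifting every R by a constant leaves S unchanged
  scores_direct <- function(I, D, R) {
    zp <- function(x) if (sqrt(mean((x - mean(x))^2)) == 0) rep(0, length(x))
    else (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    zp(I) - zp(D) - zp(R)
  }
  I <- c(1, 3, 2); D <- c(0.2, 0.1, 0.4); R <- c(0, 1, 2)
  expect_equal(scores_direct(I, D, R), scores_direct(I, D, R + 5), tolerance = 1e-12)
})

test_that("greedy pruning removes only overlap strictly above the threshold", {
  # all identical: exactly one survivor
  same <- make_pool(list(c("a", "b"), c("a", "b"), c("a", "b")))
  expect_length(prune_pool(same), 1L)

  # pairwise disjoint: all survive
  disj <- make_pool(list(c("a", "b"), c("c", "d"), c("e", "f")))
  expect_length(prune_pool(disj), 3L)

  # J exactly 0.7 is kept: |A| = 17, |B| = 17, overlap 14 -> 14/20
  A <- sprintf("x%02d", 1:17)
  B <- c(sprintf("x%02d", 1:14), "y1", "y2", "y3")
  expect_equal(jaccard(A, B), 0.7)
  expect_length(prune_pool(make_pool(list(A, B))), 2L)
})

test_that("greedy pruning follows the scored pick order", {
  # S(A) > S(B) > S(C); J(A,B) = 0.8 removes B; J(A,C) small keeps C
  A <- sprintf("a%02d", 1:18)
  B <- c(sprintf("a%02d", 1:16), "b1", "b2")          # J(A,B) = 16/20 = 0.8
  C <- c(sprintf("a%02d", 1:2), sprintf("c%02d", 1:10))  # J(A,C) = 2/28 < 0.7
  pool <- make_pool(list(A, B, C))
  sc <- composite_scores(pool)
  sc$S <- c(3, 2, 1)
  kept <- prune_pool(pool, sc)
  expect_equal(lapply(kept, `[[`, "genes"), list(sort(A), sort(C)))

  # permuting candidate order leaves the survivor set unchanged
  pool_perm <- make_pool(list(C, A, B))
  sc_perm <- composite_scores(pool_perm)
  sc_perm$S <- c(1, 3, 2)
  kept_perm <- prune_pool(pool_perm, sc_perm)
  expect_setequal(lapply(kept_perm, function(x) paste(x$genes, collapse = ",")),
                  lapply(kept, function(x) paste(x$genes, collapse = ",")))
})

test_that("pools are pruned independently per k", {
  pools <- list(`5` = make_pool(list(c("a", "b"), c("a", "b"))),
                `9` = make_pool(list(c("c", "d"), c("c", "d"))))
  kept <- prune_all(pools)
  expect_equal(lengths(kept), c(`5` = 1L, `9` = 1L))
  # a k absent from the pools contributes nothing, without error
  expect_length(prune_all(pools[1]), 1L)
  expect_length(prune_all(list()), 0L)
})
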