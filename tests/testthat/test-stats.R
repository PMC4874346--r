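test_that("kruskal_wallis reproduces the rank-sum formula", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_perm_test(res)
  expect_equal(res$statistic, 3.857, tolerance = 5e-4)
  expect_equal(res$df, 1L)
  # cross-check against the stats implementation, with ties
  g <- list(c(1, 2, 2, 5), c(3, 3, 7), c(2, 8, 8, 8))
  ref <- stats::kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
  mine <- kruskal_wallis(g)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # identical groups have H = 0 after tie correction
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  expect_error(kruskal_wallis(list(c(1, 2, 3))), "2 groups")
})

test_that("Monte-Carlo Kruskal-Wallis agrees with full enumeration", {
  g <- list(c(1.2, 3.4, 2.1), c(5.6, 4.3))
  obs <- kruskal_wallis(g)$statistic
  vals <- unlist(g)
  exact <- mean(vapply(all_perms(vals), function(v) {
    kruskal_wallis(list(v[1:3], v[4:5]))$statistic >= obs - 1e-12
  }, logical(1)))
  B <- 4000
  mc <- kruskal_wallis(g, method = "monte_carlo", n_perm = B, seed = 3)
  se <- sqrt(exact * (1 - exact) / B)
  expect_lt(abs(mc$p_value - exact), 3 * se + 1 / (B + 1))
  # bit-identical under the same seed
  mc2 <- kruskal_wallis(g, method = "monte_carlo", n_perm = B, seed = 3)
  expect_identical(mc$p_value, mc2$p_value)
})

test_that("DSCF posthoc p-values behave under exchangeable nulls", {
  # identical groups: every permutation is as extreme, p = 1
  g <- list(a = c(2, 2, 2, 2), b = c(2, 2, 2, 2), c = c(2, 2, 2, 2))
  res <- dscf_posthoc(g, n_perm = 200, seed = 1)
  expect_true(all(res$pairs$p.value == 1))
  expect_equal(diag(res$p_matrix), c(a = 1, b = 1, c = 1))
  expect_equal(res$p_matrix, t(res$p_matrix))

  # complete separation: the permutation p equals the enumerated share of
  # equally extreme re-splits of the pooled pair (2 of choose(8,4) = 70)
  g2 <- list(lo = c(1, 1, 1, 1), hi = c(9, 9, 9, 9), mid = c(5, 5, 5, 5))
  B <- 2000
  res2 <- dscf_posthoc(g2, n_perm = B, seed = 2)
  p_lo_hi <- res2$pairs$p.value[res2$pairs$group1 == "lo" &
                                  res2$pairs$group2 == "hi"]
  exact <- 2 / 70
  expect_lt(abs(p_lo_hi - exact), 3 * sqrt(exact * (1 - exact) / B) + 1 / (B + 1))
  # tiny groups are skipped with a warning
  w <- testthat::capture_warnings(
    dscf_posthoc(list(a = 1, b = c(1, 2, 3), c = c(4, 5, 6)), n_perm = 50))
  expect_true(any(grepl("skipped", w)))
  expect_error(dscf_posthoc(list(a = 1:3, b = 4:6)), ">= 3 groups")
})

test_that("jonckheere_terpstra counts ordered concordant pairs", {
  res <- jonckheere_terpstra(list(1, 2, 3), n_perm = 500, seed = 1)
  expect_perm_test(res)
  expect_equal(res$statistic, 3)
  # all observations equal: JT = half the cross-pairs, p ~ 1
  res_t <- jonckheere_terpstra(list(c(5, 5), c(5, 5)), n_perm = 500, seed = 1)
  expect_equal(res_t$statistic, 2)
  expect_equal(res_t$p_value, 1)
  # reversing the group order maps JT to total cross-pairs minus JT
  g <- list(c(1.5, 2.5, 0.5), c(3.5, 1.1), c(4.2, 2.2, 6.0))
  fw <- jonckheere_terpstra(g, n_perm = 10, seed = 1)
  bw <- jonckheere_terpstra(rev(g), n_perm = 10, seed = 1)
  sizes <- lengths(g)
  total <- sum(outer(sizes, sizes)[upper.tri(outer(sizes, sizes))])
  expect_equal(fw$statistic + bw$statistic, total)
})

test_that("Monte-Carlo JT p agrees with full enumeration on a small case", {
  g <- list(c(3, 1), c(4, 2), c(6, 5))
  obs <- jonckheere_terpstra(g, n_perm = 10, seed = 1)$statistic
  vals <- unlist(g)
  stats_all <- vapply(all_perms(vals), function(v) {
    jonckheere_terpstra(list(v[1:2], v[3:4], v[5:6]),
                        n_perm = 2, seed = 1)$statistic
  }, numeric(1))
  exact <- min(1, 2 * min(mean(stats_all >= obs), mean(stats_all <= obs)))
  B <- 4000
  mc <- jonckheere_terpstra(g, n_perm = B, seed = 9)
  se <- sqrt(exact * (1 - exact) / B)
  expect_lt(abs(mc$p_value - exact), 3 * se + 2 / (B + 1))
})

test_that("skillings_mack reduces to Friedman on complete balanced blocks", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(stats::rnorm(6 * 4), nrow = 6)
    df <- data.frame(y = as.vector(m),
                     block = rep(seq_len(6), 4),
                     trt = rep(seq_len(4), each = 6))
    sm <- skillings_mack(df$y, df$block, df$trt, n_perm = 10, seed = 1)
    fr <- stats::friedman.test(m)
    expect_equal(sm$statistic, unname(fr$statistic), tolerance = 1e-10)
    expect_equal(sm$df, unname(fr$parameter))
  }
})

test_that("skillings_mack handles constant blocks and missing levels", {
  # within-block constant data carries no evidence: statistic 0
  df <- data.frame(y = rep(c(1, 5, 3), each = 3),
                   block = rep(1:3, each = 3), trt = rep(1:3, 3))
  sm <- skillings_mack(df$y, df$block, df$trt, n_perm = 100, seed = 1)
  expect_equal(sm$statistic, 0)
  expect_equal(sm$p_value, 1)
  # incomplete blocks are usable; single-observation blocks are dropped
  y <- c(1, 2, 2, 3, 5, 9, 4)
  bl <- c("a", "a", "b", "b", "c", "c", "d")
  tr <- c(1, 2, 1, 3, 2, 3, 1)
  expect_warning(sm2 <- skillings_mack(y, bl, tr, n_perm = 100, seed = 2),
                 "excluded")
  expect_perm_test(sm2)
  expect_error(suppressWarnings(
    skillings_mack(c(1, 2), c("a", "b"), c(1, 1), n_perm = 10)),
    "treatment levels")
})

test_that("fisher_exact_rxc matches hypergeometric enumeration", {
  # 2x2 diagonal table: only the two perfectly sorted tables are as
  # improbable as observed -> p = 2 * dhyper(5, 5, 5, 5)
  tab <- matrix(c(5, 0, 0, 5), 2, 2)
  probs <- stats::dhyper(0:5, 5, 5, 5)
  p_exact <- sum(probs[probs <= stats::dhyper(5, 5, 5, 5) + 1e-12])
  expect_equal(p_exact, 2 / 252, tolerance = 1e-12)
  res <- fisher_exact_rxc(tab)
  expect_equal(res$p_value, p_exact, tolerance = 1e-9)
  expect_equal(res$method, "EXACT_ENUMERATION")
  # proportional rows: the observed table is the mode, p = 1
  expect_equal(fisher_exact_rxc(matrix(c(4, 8, 2, 4), 2, 2))$p_value, 1)
  # Monte-Carlo route converges to the enumerated p and is seed-stable
  B <- 20000
  mc <- fisher_exact_rxc(tab, method = "monte_carlo", n_draws = B, seed = 4)
  expect_lt(abs(mc$p_value - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / B) + 2 / (B + 1))
  expect_identical(
    mc$p_value,
    fisher_exact_rxc(tab, method = "monte_carlo", n_draws = B, seed = 4)$p_value)
  expect_error(fisher_exact_rxc(matrix(c(0, 0, 1, 2), 2, 2)), "margins")
  expect_error(fisher_exact_rxc(matrix(c(1.5, 1, 1, 1), 2, 2)), "integers")
})

test_that("mantel_test aligns labels and respects affine invariance", {
  set.seed(21)
  pts <- matrix(rnorm(12), ncol = 2,
                dimnames = list(paste0("sp", 1:6), NULL))
  D1 <- as.matrix(dist(pts))
  # self-correlation is exactly 1
  expect_equal(mantel_test(D1, D1, n_perm = 99, seed = 1)$statistic, 1)
  # positive affine transforms of the off-diagonals keep r = 1
  D2 <- 3.2 * D1 + 0.7
  diag(D2) <- 0
  expect_equal(mantel_test(D1, D2, n_perm = 99, seed = 1)$statistic, 1)
  # alignment is by label, not position
  idx <- c(4, 1, 6, 2, 3, 5)
  D1_shuf <- D1[idx, idx]
  r_ref <- mantel_test(D1, D2, n_perm = 99, seed = 1)$statistic
  expect_equal(mantel_test(D1_shuf, D2, n_perm = 99, seed = 1)$statistic,
               r_ref)
  bad <- D1
  rownames(bad) <- colnames(bad) <- paste0("x", 1:6)
  expect_error(mantel_test(D1, bad, n_perm = 9), "label mismatch")
  asym <- D1; asym[1, 2] <- asym[1, 2] + 1
  expect_error(mantel_test(asym, D2, n_perm = 9), "symmetric")
})

test_that("mantel_test agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(5)
  p1 <- matrix(rnorm(14), ncol = 2)
  p2 <- p1 + matrix(rnorm(14, sd = 0.4), ncol = 2)
  labs <- paste0("s", 1:7)
  D1 <- as.matrix(dist(p1)); dimnames(D1) <- list(labs, labs)
  D2 <- as.matrix(dist(p2)); dimnames(D2) <- list(labs, labs)
  mine <- mantel_test(D1, D2, n_perm = 9999, seed = 2)
  ref <- vegan::mantel(as.dist(D1), as.dist(D2), permutations = 9999)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(mine$p_value - ref$signif), 0.02)
})

test_that("Monte-Carlo Mantel p agrees with exact label enumeration", {
  set.seed(8)
  labs <- paste0("s", 1:4)
  D1 <- as.matrix(dist(matrix(rnorm(8), ncol = 2)))
  D2 <- as.matrix(dist(matrix(rnorm(8), ncol = 2)))
  dimnames(D1) <- dimnames(D2) <- list(labs, labs)
  lt <- lower.tri(D1)
  r_obs <- cor(D1[lt], D2[lt])
  r_all <- vapply(all_perms(1:4), function(p) {
    cor(D1[lt], D2[p, p][lt])
  }, numeric(1))
  exact <- mean(r_all >= r_obs - 1e-12)
  B <- 4000
  mc <- mantel_test(D1, D2, n_perm = B, seed = 13)
  expect_lt(abs(mc$p_value - exact),
            3 * sqrt(exact * (1 - exact) / B) + 1 / (B + 1))
})

test_that("tidy and glance summarise permutation tests", {
  res <- jonckheere_terpstra(list(c(1, 2), c(3, 4)), n_perm = 99, seed = 1)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$statistic, res$statistic)
  expect_equal(td$n_permutations, 99L)
  expect_named(glance(res), names(td))
  pairs <- tidy(dscf_posthoc(list(a = 1:4, b = 2:5, c = 3:6),
                             n_perm = 49, seed = 1))
  expect_true(all(c("group1", "group2", "p.value") %in% names(pairs)))
})
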