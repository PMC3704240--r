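test_that("exact Wilcoxon matches full enumeration of splits", {
  # separated groups: only the two extreme splits are as extreme
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  # identical multisets give p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # degenerate: everything identical
  w <- wilcoxon_rank_sum(c(2, 2), c(2, 2))
  expect_true(w$degenerate)
  expect_equal(w$p_value, 1)
  # random small groups vs brute-force enumeration oracle (with ties)
  set.seed(17)
  for (rep in 1:10) {
    a <- sample(1:6, 4, replace = TRUE)
    b <- sample(1:6, 4, replace = TRUE)
    r <- rank(c(a, b))
    W <- sum(r[1:4])
    sums <- combn(r, 4, sum)
    p_oracle <- min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, p_oracle)
  }
})

test_that("normal-approximation Wilcoxon is sane on large samples", {
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30) + 2
  w <- wilcoxon_rank_sum(a, b)
  expect_equal(w$method, "normal")
  expect_lt(w$p_value, 1e-5)
  # agrees with stats::wilcox.test within approximation differences
  ref <- wilcox.test(a, b)$p.value
  expect_equal(w$p_value, ref, tolerance = 0.01)
})

test_that("rank Levene detects a 10x spread difference and respects the null", {
  set.seed(31)
  hits <- 0
  for (i in 1:50) {
    v <- c(rnorm(50, sd = 1), rnorm(50, sd = 10))
    g <- rep(c("a", "b"), each = 50)
    if (rank_levene(v, g)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 45)  # >= 90% power at this spread
  # equal constant groups are degenerate with p = 1
  lev <- rank_levene(c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_true(lev$degenerate)
  expect_equal(lev$p_value, 1)
})

test_that("rank tests hold their type-I error under the null", {
  set.seed(55)
  n_rep <- 400
  rej_w <- rej_l <- 0
  for (i in 1:n_rep) {
    v <- rnorm(36)
    g <- rep(c("a", "b", "c"), each = 12)
    if (wilcoxon_rank_sum(v[1:12], v[13:24])$p_value < 0.05) rej_w <- rej_w + 1
    if (rank_levene(v, g)$p_value < 0.05) rej_l <- rej_l + 1
  }
  tol <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(rej_w / n_rep, 0.05 + tol)
  expect_lt(rej_l / n_rep, 0.05 + tol)
})

test_that("Kruskal-Wallis block test has blocks-minus-one df and power", {
  v <- rnorm(24); b <- rep(1:3, each = 8)
  kt <- kruskal_wallis_blocks(v, b)
  expect_equal(kt$df, 2)
  expect_error(kruskal_wallis_blocks(v, rep(1, 24)), ">= 2 blocks")
  set.seed(7)
  hits <- 0
  for (i in 1:100) {
    v <- c(rnorm(8), rnorm(8, mean = 3))
    if (kruskal_wallis_blocks(v, rep(1:2, each = 8))$p_value < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("outlier screening flags by single-pass z score", {
  expect_equal(sum(screen_outliers(rep(5, 10))$is_outlier), 0)
  x <- c(rep(10, 9), 0)
  # z of the 0 is about -2.85: flagged at k = 2.5, not at k = 4
  expect_true(screen_outliers(x, k = 2.5)$is_outlier[10])
  expect_false(any(screen_outliers(x, k = 4)$is_outlier))
  # retained + flagged partition the input
  sc <- screen_outliers(x, k = 2.5)
  expect_equal(sort(c(sc$retained, sc$flagged)), sort(x))
})

test_that("Bonferroni z cutoff matches normal quantiles and is monotone", {
  expect_equal(bonferroni_cutoff(0.05, 1), qnorm(0.975))
  expect_equal(bonferroni_cutoff(0.05, 100), 3.48, tolerance = 0.005)
  fams <- c(1, 10, 50, 100, 500)
  expect_true(all(diff(bonferroni_cutoff(0.05, fams)) > 0))
})

test_that("line classification labels sides correctly", {
  tab <- tiny_table(anc = c(0.97, 1.00, 1.03),
                    ma = list(L1 = c(1.00), L2 = c(0.20), L3 = c(1.80)))
  cl <- classify_lines(tab, "liquid_growth", cutoff = 3.48)
  calls <- setNames(cl$calls$direction, cl$calls$line_id)
  expect_equal(unname(calls[c("L1", "L2", "L3")]), c("none", "low", "high"))
  expect_equal(unname(cl$bounds),
               mean(c(0.97, 1, 1.03)) + c(-1, 1) * 3.48 * sd(c(0.97, 1, 1.03)))
  # z = 0.85 with ancestor (1, 0.03): |z| = 5 > 3.48 -> low
  tab2 <- tiny_table(anc = c(0.97, 1.00, 1.03), ma = list(L1 = 0.85))
  sd_anc <- sd(c(0.97, 1, 1.03))
  cl2 <- classify_lines(tab2, "liquid_growth", cutoff = 3.48)
  expect_equal(cl2$calls$direction, "low")
  expect_equal(cl2$calls$z_score, (0.85 - 1) / sd_anc)
})

test_that("p-value adjustment reproduces hand-computed BH and Bonferroni", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.04), 0.04)
  expect_equal(adjust_pvalues(rep(0.01, 3), method = "bonferroni"),
               rep(0.03, 3))
  p <- c(0.001, 0.02, 0.5)
  expect_true(all(adjust_pvalues(p) >= p))
})
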