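test_that("Spearman matrix handles monotone, reversed and tied data", {
  x <- c(1, 2, 3, 4, 5, 6)
  m <- cbind(a = x, b = x^2, c = -x + 10, d = c(2, 1, 4, 3, 6, 5))
  sp <- spearman_matrix(m)
  expect_equal(sp$r["a", "b"], 1)
  expect_equal(sp$r["a", "c"], -1)
  expect_equal(diag(sp$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(sp$r, t(sp$r))
  # hand-rank oracle for the non-trivial pair
  expect_equal(sp$r["a", "d"], cor(rank(x), rank(c(2, 1, 4, 3, 6, 5))))
  # constant trait flagged, not an error
  m2 <- cbind(m, e = rep(1, 6))
  sp2 <- spearman_matrix(m2)
  expect_true(sp2$constant["e"])
  expect_true(is.na(sp2$r["a", "e"]))
})

test_that("effective number of traits spans its bounds", {
  expect_equal(effective_traits(diag(8))$n_eff, 8)
  ones <- matrix(1, 8, 8)
  expect_equal(effective_traits(ones)$n_eff, 1)
  # permutation invariance
  tabs <- dicty_ma_tables()
  C <- tabs$correlations
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  expect_equal(effective_traits(C[perm, perm])$n_eff,
               effective_traits(C)$n_eff)
  # increasing a correlation (others fixed) lowers n_eff
  C2 <- diag(8); C2[1, 2] <- C2[2, 1] <- 0.5
  expect_lt(effective_traits(C2)$n_eff, 8)
  expect_error(effective_traits(matrix(c(1, 0.2, 0.3, 1), 2, 2)), "symmetric")
})

test_that("component rate inverts the mutation-free proportion exactly", {
  cr <- component_rate(85, 90, 994)
  expect_equal((1 - cr$mu_hat)^994 * 90, 90 - 85, tolerance = 1e-9)
  expect_equal(cr$lambda_hat, 994 * (1 - (5 / 90)^(1 / 994)))
  expect_equal(component_rate(0, 90, 994)$mu_hat, 0)
  expect_error(component_rate(90, 90, 994), "unbounded")
})

test_that("Poisson-binomial expectation is exact and sums to the line count", {
  # all-zero probabilities concentrate at category 0
  d0 <- expected_affected_distribution(rep(0, 8), 90)
  expect_equal(d0$expected, c(90, rep(0, 8)))
  # matches an independent closed form for two components
  d2 <- expected_affected_distribution(c(0.3, 0.6), 10)
  expect_equal(d2$prob, c(0.7 * 0.4, 0.3 * 0.4 + 0.7 * 0.6, 0.3 * 0.6))
  # reference counts: expectation sums to 90 exactly
  dref <- expected_affected_distribution(ref_k_sig / 90, 90)
  expect_equal(sum(dref$expected), 90)
})

test_that("randomization tests converge to the analytic null and stay calm under it", {
  # all-zero significant counts: every simulation identical, chi2 = 0
  calls0 <- matrix(FALSE, 20, 4)
  r0 <- randomization_test_A(calls0, n_sims = 120, seed = 1)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$significant_fraction, 0)
  # mean simulated counts approach the Poisson-binomial expectation
  calls <- calls_matrix(
    row_sums = rep(c(0, 1, 2, 3), times = c(10, 20, 40, 20)),
    col_sums = c(50, 55, 30, 25))
  ra <- randomization_test_A(calls, n_sims = 4000, seed = 2)
  ex <- expected_affected_distribution(colSums(calls) / nrow(calls),
                                       nrow(calls))$expected
  expect_true(all(abs(ra$mean_expected - ex) < 3 * sqrt(pmax(ex, 0.1)) / sqrt(40) + 0.5))
  # test B mean counts match its own Poisson-binomial with p = 1 - exp(-lambda)
  lam <- c(0.5, 1, 0.2, 1.5)
  set.seed(44)
  obs <- mafitkit:::tally_categories(rowSums(matrix(rpois(90 * 4, rep(lam, each = 90)), 90, 4) > 0), 4)
  rb <- randomization_test_B(lam, obs, n_lines = 90, n_sims = 3000, seed = 3)
  exb <- expected_affected_distribution(1 - exp(-lam), 90)$expected
  expect_true(all(abs(rb$mean_expected - exb) < 3 * sqrt(pmax(exb, 0.1)) / sqrt(30) + 0.5))
})

test_that("calls_matrix reproduces requested margins and rejects impossible ones", {
  m <- calls_matrix(rep(c(0, 1, 2, 3, 4, 5, 6, 7), times = c(0, 1, 4, 13, 24, 34, 11, 3)),
                    ref_k_sig)
  expect_equal(unname(colSums(m)), unname(ref_k_sig))
  expect_equal(mafitkit:::tally_categories(rowSums(m), 8),
               ref_observed_categories)
  expect_error(calls_matrix(c(3, 3), c(1, 1)), "balance|infeasible")
})

test_that("ad hoc lower bound solves both readings of the zero-class statement", {
  b <- adhoc_lower_bound_U(90, 994, 0.95)
  expect_equal(b$UG[1], -log(1 - 0.05^(1 / 90)), tolerance = 1e-6)
  expect_equal(b$UG[2], -log(1 - 0.95^(1 / 90)), tolerance = 1e-6)
  expect_equal(b$UG[1], 3.42, tolerance = 0.005)
  expect_equal(b$UG[2], 7.47, tolerance = 0.005)
  # single line reduction: (1 - e^-m) = level
  b1 <- adhoc_lower_bound_U(1, 100, 0.95)
  expect_equal(1 - exp(-b1$UG[2]), 0.95, tolerance = 1e-6)
})

test_that("cubic regression finds interior optima and flags nonlinearity", {
  x <- seq(0, 2, length.out = 25)
  y <- -(x - 1)^2
  cf <- cubic_optimum(x, y)
  expect_equal(cf$optimum, 1, tolerance = 1e-6)
  expect_lt(cf$f_test$p, 1e-10)
  # noiseless cubic with known stationary points: max of x^3 - 3x at x = -1
  x2 <- seq(-2, 2, length.out = 30)
  y2 <- x2^3 - 3 * x2
  expect_equal(cubic_optimum(x2, y2)$optimum, -1, tolerance = 1e-6)
  # pure line: no interior optimum
  expect_true(is.na(cubic_optimum(x, 2 * x + 1)$optimum))
})
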