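#' Spearman correlation matrix among fitness components
#'
#' Pairwise Spearman correlations (midranks) of line means across traits,
#' with per-pair p values adjusted by Benjamini-Hochberg across all pairs.
#'
#' @param line_means numeric matrix, lines in rows, traits in columns (see
#'   [line_trait_matrix()]); >= 4 complete lines required.
#' @return list with `r` (correlation matrix, unit diagonal), `p` (raw
#'   p values), `p_adj` (BH-adjusted), `constant` (traits with zero
#'   variance, whose correlations are `NA` and flagged).
#' @export
spearman_matrix <- function(line_means) {
  m <- as.matrix(line_means)
  if (nrow(m) < 4) stop("need >= 4 lines")
  nt <- ncol(m)
  constant <- apply(m, 2, function(x) var(x, na.rm = TRUE) == 0)
  r <- diag(nt); p <- matrix(NA_real_, nt, nt)
  dimnames(r) <- dimnames(p) <- list(colnames(m), colnames(m))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    if (constant[i] || constant[j]) { r[i, j] <- r[j, i] <- NA; next }
    ct <- suppressWarnings(
      cor.test(m[, i], m[, j], method = "spearman", exact = FALSE))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  up <- upper.tri(p)
  p_adj <- p
  p_adj[up] <- adjust_pvalues(p[up])
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(r = r, p = p, p_adj = p_adj, constant = constant)
}

#' Effective number of traits from a correlation matrix
#'
#' `N_eff = N - Var(lambda)`, where `lambda` are the eigenvalues of the
#' `N x N` trait correlation matrix. Under independence all eigenvalues are
#' 1 and `N_eff = N`; under perfect correlation one eigenvalue is `N` and
#' `N_eff = 1`. The eigenvalue mean is exactly 1, and the variance uses
#' divisor `N` by default (`divisor = "n-1"` is also accepted; both round to
#' the same headline value on the reference data).
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param divisor `"n"` (population variance, default) or `"n-1"`.
#' @return list with `eigenvalues`, `var_lambda`, `n_eff`.
#' @export
effective_traits <- function(corr, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr), tol = 1e-8)) stop("matrix must be symmetric")
  if (any(abs(diag(corr) - 1) > 1e-8)) stop("diagonal must be 1")
  N <- ncol(corr)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  vl <- sum((ev - mean(ev))^2) / if (divisor == "n") N else N - 1
  list(eigenvalues = ev, var_lambda = vl, n_eff = N - vl)
}

#' Per-component mutation-rate point estimate
#'
#' Inverts the expected proportion of mutation-free lines,
#' `(1 - mu)^G = (n - k)/n`, where `k` of `n` lines are significantly
#' different from the ancestor for the component, giving the per-generation
#' rate `mu_hat` and the expected mutations per line
#' `lambda_hat = G * mu_hat`.
#'
#' @param k_sig number of significantly different lines (`0 <= k_sig < n`).
#' @param n_lines total number of MA lines.
#' @param G generations.
#' @param trait optional label.
#' @return list with `trait`, `k_sig`, `n_lines`, `mu_hat`, `lambda_hat`.
#' @export
component_rate <- function(k_sig, n_lines = 90, G = 994,
                           trait = NA_character_) {
  if (k_sig < 0 || k_sig > n_lines) stop("k_sig must lie in [0, n_lines]")
  if (k_sig == n_lines)
    stop("all lines affected: rate unbounded under the inversion")
  mu <- 1 - ((n_lines - k_sig) / n_lines)^(1 / G)
  list(trait = trait, k_sig = k_sig, n_lines = n_lines, mu_hat = mu,
       lambda_hat = G * mu)
}

#' Exact Poisson-binomial distribution of affected components per line
#'
#' Given independent per-component probabilities `p` that a line is scored
#' as significantly different, computes the exact distribution of the number
#' of affected components per line (by iterated convolution) and scales it
#' by the number of lines. This is the analytic limit of both randomization
#' tests' category means.
#'
#' @param p vector of per-component affect probabilities in `[0, 1]`.
#' @param n_lines number of lines to scale by (default 90).
#' @return data frame with `affected` (0..length(p)), `prob`, `expected`
#'   (`prob * n_lines`).
#' @export
expected_affected_distribution <- function(p, n_lines = 90) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  data.frame(affected = seq_along(pmf) - 1L, prob = pmf,
             expected = pmf * n_lines)
}

# chi-squared of observed category counts against a simulated expectation,
# excluding zero-expectation categories; df kept at the full category count
# minus one as in the reference analysis
category_chi2 <- function(obs, expected, df = length(obs) - 1) {
  use <- expected > 0
  stat <- sum((obs[use] - expected[use])^2 / expected[use])
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# shared core of the two randomization tests
run_randomization <- function(observed_counts, simulate_counts, n_sims,
                              seed, n_traits) {
  if (n_sims < 100) warning("n_sims < 100: tail fraction will be unstable")
  set.seed(seed)
  nc <- n_traits + 1
  sims <- matrix(0, n_sims, nc)
  n_sig <- 0
  for (s in seq_len(n_sims)) {
    cnt <- simulate_counts()
    sims[s, ] <- cnt
    if (category_chi2(observed_counts, cnt, df = n_traits)$p < 0.05)
      n_sig <- n_sig + 1
  }
  mean_counts <- colMeans(sims)
  overall <- category_chi2(observed_counts, mean_counts, df = n_traits)
  list(observed = observed_counts, mean_expected = mean_counts,
       chi2 = overall$stat, df = overall$df, p = overall$p,
       n_sims = n_sims, n_significant_sims = n_sig,
       significant_fraction = n_sig / n_sims)
}

tally_categories <- function(affected_per_line, n_traits)
  tabulate(factor(affected_per_line, levels = 0:n_traits), nbins = n_traits + 1)

#' Randomization test A: reshuffle significant calls across lines
#'
#' Holds the per-trait numbers of significantly different lines fixed at
#' their observed values and, in each simulation, reassigns each trait's
#' significant labels to lines uniformly at random without replacement.
#' Each simulated dataset's category counts (lines with 0..N affected
#' components) serve as the expectation in a chi-squared comparison against
#' the observed counts; the reported fraction of significant simulations is
#' the test output (a fraction near the nominal 5% indicates independence).
#'
#' @param calls logical matrix, lines x traits, `TRUE` where the line is
#'   significantly different from the ancestor for that trait (see
#'   [calls_matrix()]).
#' @param n_sims number of randomizations (default 1000).
#' @param seed RNG seed.
#' @return list (see [run_randomization] fields): observed and mean
#'   simulated category counts, overall chi-squared vs the mean expectation,
#'   and `significant_fraction`.
#' @export
randomization_test_A <- function(calls, n_sims = 1000, seed = 1) {
  calls <- as.matrix(calls)
  n <- nrow(calls); nt <- ncol(calls)
  k <- colSums(calls)
  obs <- tally_categories(rowSums(calls), nt)
  run_randomization(obs, function() {
    m <- matrix(FALSE, n, nt)
    for (t in seq_len(nt)) if (k[t] > 0) m[sample.int(n, k[t]), t] <- TRUE
    tally_categories(rowSums(m), nt)
  }, n_sims, seed, nt)
}

#' Randomization test B: Poisson mutation occurrence per component
#'
#' Parameterises a Poisson distribution for each fitness component from its
#' point-estimate mutation rate (see [component_rate()]), simulates mutation
#' counts per line and component, scores a component affected when at least
#' one mutation occurred, and compares category counts to the observed as in
#' [randomization_test_A()].
#'
#' @param lambda vector of expected mutations per line per component
#'   (`lambda_hat` from [component_rate()]).
#' @param observed_counts observed category counts (lines with 0..N affected
#'   components), length `length(lambda) + 1`.
#' @param n_lines number of MA lines.
#' @param n_sims,seed as in [randomization_test_A()].
#' @return as [randomization_test_A()].
#' @export
randomization_test_B <- function(lambda, observed_counts, n_lines = 90,
                                 n_sims = 1000, seed = 1) {
  nt <- length(lambda)
  stopifnot(length(observed_counts) == nt + 1)
  run_randomization(observed_counts, function() {
    m <- matrix(rpois(n_lines * nt, rep(lambda, each = n_lines)),
                n_lines, nt) > 0
    tally_categories(rowSums(m), nt)
  }, n_sims, seed, nt)
}

#' Reconstruct a calls matrix from its margins
#'
#' Builds a binary lines x traits matrix with prescribed per-trait totals
#' (column sums) and per-line affected-component counts (row sums), using
#' the greedy Gale-Ryser construction (each row's ones go to the columns
#' with the largest remaining capacity). Errors if the margins are
#' infeasible.
#'
#' @param row_sums integer vector of affected components per line.
#' @param col_sums integer vector of significant lines per trait.
#' @return logical matrix with the requested margins.
#' @export
calls_matrix <- function(row_sums, col_sums) {
  if (sum(row_sums) != sum(col_sums)) stop("margins do not balance")
  n <- length(row_sums); nt <- length(col_sums)
  m <- matrix(FALSE, n, nt)
  rem <- as.numeric(col_sums)
  for (i in order(row_sums, decreasing = TRUE)) {
    r <- row_sums[i]
    if (r == 0) next
    pick <- order(rem, decreasing = TRUE)[seq_len(r)]
    if (any(rem[pick] <= 0)) stop("infeasible margins")
    m[i, pick] <- TRUE
    rem[pick] <- rem[pick] - 1
  }
  if (any(rem != 0)) stop("infeasible margins")
  colnames(m) <- names(col_sums)
  m
}

#' Ad hoc lower bound on the genomic mutation rate
#'
#' When every MA line shows at least one affected fitness component, the
#' mutation-free class was never observed. The bound solves, for the
#' per-generation rate `U`, the statement that the probability of obtaining
#' zero mutation-free lines among `n_lines` is at the confidence level.
#' The statement admits two readings, and both are returned:
#' reading (i) solves `(1 - exp(-U*G))^n = 1 - confidence` (the probability
#' of zero mutation-free lines is small, 5%); reading (ii) solves
#' `(1 - exp(-U*G))^n = confidence` (that probability reaches 95%).
#'
#' @param n_lines number of MA lines (default 90).
#' @param G generations.
#' @param confidence confidence level (default 0.95).
#' @return data frame with `reading`, `UG` (expected mutations per line) and
#'   `U` per generation for both readings.
#' @export
adhoc_lower_bound_U <- function(n_lines = 90, G = 994, confidence = 0.95) {
  solve_for <- function(target) {
    f <- function(m) n_lines * log1p(-exp(-m)) - log(target)
    uniroot(f, c(1e-8, 50), tol = 1e-12)$root
  }
  m1 <- solve_for(1 - confidence)
  m2 <- solve_for(confidence)
  data.frame(reading = c("prob_zero_small", "prob_zero_large"),
             UG = c(m1, m2), U = c(m1, m2) / G)
}

#' Cubic regression screen for stabilizing selection
#'
#' Least-squares cubic of a fitness proxy (e.g. total spores) on a component
#' value, the F-test of the quadratic-plus-cubic terms against the linear
#' model, and the location of a local maximum of the fitted cubic inside the
#' data range (absent if the derivative has no real root there or the
#' stationary point is a minimum).
#'
#' @param x component values (>= 8 points).
#' @param y fitness-proxy values.
#' @return list with `coefficients` (intercept..cubic), `f_test`
#'   (statistic, df, p for nonlinearity), `optimum` (x of interior local
#'   maximum or `NA`), `fitted` function.
#' @export
cubic_optimum <- function(x, y) {
  if (length(x) < 8) stop("need >= 8 points")
  fit1 <- lm(y ~ x)
  fit3 <- lm(y ~ x + I(x^2) + I(x^3))
  cmp <- anova(fit1, fit3)
  b <- coef(fit3); b[is.na(b)] <- 0
  # derivative 3 b3 x^2 + 2 b2 x + b1 = 0
  opt <- NA_real_
  disc <- (2 * b[3])^2 - 4 * (3 * b[4]) * b[2]
  roots <- if (abs(b[4]) > 1e-12 && disc >= 0) {
    (-2 * b[3] + c(-1, 1) * sqrt(disc)) / (2 * 3 * b[4])
  } else if (abs(b[4]) <= 1e-12 && abs(b[3]) > 1e-12) {
    -b[2] / (2 * b[3])
  } else numeric(0)
  for (r in roots) {
    if (r >= min(x) && r <= max(x) && (2 * b[3] + 6 * b[4] * r) < 0) {
      opt <- r; break
    }
  }
  list(coefficients = unname(b),
       f_test = list(statistic = cmp$F[2], df = c(cmp$Df[2], cmp$Res.Df[2]),
                     p = cmp$`Pr(>F)`[2]),
       optimum = opt,
       fitted = function(xx) b[1] + b[2] * xx + b[3] * xx^2 + b[4] * xx^3)
}
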