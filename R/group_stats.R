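#' Two-sample Wilcoxon rank-sum test
#'
#' Midranks are used for ties. For combined sample sizes up to `exact_max`
#' the null distribution of the rank sum is obtained by exact enumeration of
#' all splits (so the test remains exact under ties); larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param exact_max combined-size threshold for exact enumeration.
#' @return list of class `ma_test` with `test_name`, `statistic` (rank sum of
#'   `a`), `p_value`, `method` ("exact" or "normal"), and `degenerate` flag
#'   (all pooled values identical, p = 1 by convention).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 20) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  if (length(unique(pooled)) == 1) {
    return(ma_test("wilcoxon_rank_sum", W, 1, method = "degenerate",
                   degenerate = TRUE))
  }
  if (n <= exact_max) {
    sums <- utils::combn(r, na, sum)
    lo <- mean(sums <= W + 1e-9); hi <- mean(sums >= W - 1e-9)
    p <- min(1, 2 * min(lo, hi))
    return(ma_test("wilcoxon_rank_sum", W, p, method = "exact"))
  }
  mu <- na * (n + 1) / 2
  ties <- table(pooled)
  sig2 <- na * (n - na) / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  ma_test("wilcoxon_rank_sum", W, min(1, 2 * pnorm(-abs(z))),
          method = "normal")
}

ma_test <- function(name, statistic, p, df = NA_real_, method = NA_character_,
                    degenerate = FALSE, adjusted_p = NA_real_) {
  structure(list(test_name = name, statistic = unname(statistic),
                 p_value = unname(p), df = df, method = method,
                 degenerate = degenerate, adjusted_p = adjusted_p),
            class = "ma_test")
}

#' @export
print.ma_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$test_name, x$statistic,
              x$p_value, if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Nonparametric (rank-based) Levene test of equal variances
#'
#' Each value is centred by its group median, the centred values are pooled
#' and converted to midranks, and a classical Levene test (one-way ANOVA on
#' absolute deviations of the ranks from their group rank means) is applied
#' to the ranks in their original groupings.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return `ma_test` with F statistic, numerator df, and p value.
#' @export
rank_levene <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (any(tabulate(groups) < 2)) stop("each group needs >= 2 values")
  med <- tapply(values, groups, median)
  centred <- values - med[groups]
  r <- rank(centred)
  gm <- tapply(r, groups, mean)
  d <- abs(r - gm[groups])
  if (all(d == 0)) {
    return(ma_test("rank_levene", 0, 1, method = "degenerate",
                   degenerate = TRUE))
  }
  fit <- anova(lm(d ~ groups))
  ma_test("rank_levene", fit$`F value`[1], fit$`Pr(>F)`[1],
          df = fit$Df[1], method = "levene_on_ranks")
}

#' Kruskal-Wallis test of block homogeneity
#'
#' Used on ancestor replicates scored in multiple assay blocks to decide
#' whether blocks may be pooled. Tie-corrected, df = blocks - 1.
#'
#' @param values numeric vector of ancestor replicate measurements.
#' @param blocks block labels, same length.
#' @return `ma_test` with chi-squared statistic, df, p value.
#' @export
kruskal_wallis_blocks <- function(values, blocks) {
  blocks <- as.factor(blocks)
  if (nlevels(droplevels(blocks)) < 2) stop("need >= 2 blocks")
  kt <- kruskal.test(values, blocks)
  ma_test("kruskal_wallis_blocks", kt$statistic, kt$p.value,
          df = unname(kt$parameter), method = "kruskal_wallis")
}

#' Screen replicate outliers by SD distance
#'
#' Flags values more than `k` SDs from the mean, with mean and SD computed
#' over all values including the candidate (single pass, no iteration).
#' With SD = 0, any discordant value has infinite z and is flagged.
#'
#' @param values numeric vector (n >= 3).
#' @param k SD multiple (default 4).
#' @return list with `retained`, `flagged` (values), `is_outlier` (logical),
#'   `z` (signed z scores), `mean`, `sd`.
#' @export
screen_outliers <- function(values, k = 4) {
  if (length(values) < 3) stop("need >= 3 values to screen outliers")
  m <- mean(values); s <- sd(values)
  z <- if (s > 0) (values - m) / s else ifelse(values == m, 0, Inf * sign(values - m))
  out <- abs(z) > k
  list(retained = values[!out], flagged = values[out], is_outlier = out,
       z = z, mean = m, sd = s)
}

#' Bonferroni-corrected per-line z cutoff
#'
#' Two-sided standard-normal quantile for a familywise level `alpha` over
#' `family_size` tests: the z with `2 * (1 - pnorm(z)) = alpha/family_size`.
#' With `alpha = 0.05` and a family of 100 tested lines this is 3.48.
#'
#' @param alpha familywise significance level.
#' @param family_size number of tests in the family.
#' @return z cutoff in ancestor-SD units.
#' @export
bonferroni_cutoff <- function(alpha = 0.05, family_size = 1) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  if (any(family_size < 1)) stop("family_size must be >= 1")
  qnorm(1 - alpha / (2 * family_size))
}

#' Classify lines against the ancestor distribution
#'
#' Computes normal-theory confidence bounds `ancestor mean +/- cutoff * SD`
#' on the relative-fitness scale and labels each MA (and control) line
#' `low`, `none` or `high` by its line-mean z score relative to the
#' ancestor distribution.
#'
#' @param table a [fitness_table()] on the relative scale.
#' @param trait trait name.
#' @param cutoff z cutoff in SD units (see [bonferroni_cutoff()]); default
#'   corresponds to a 5% familywise level over 100 lines.
#' @param groups which groups to classify.
#' @return list with `bounds` (lower, upper), `ancestor_mean`,
#'   `ancestor_sd`, `cutoff`, and `calls`: data frame (line_id, group,
#'   value, z_score, direction).
#' @export
classify_lines <- function(table, trait,
                           cutoff = bonferroni_cutoff(0.05, 100),
                           groups = c("MA", "control")) {
  lv <- line_values(table, trait)
  m <- mean(lv$ancestor); s <- sd(lv$ancestor)
  if (!is.finite(s)) stop("ancestor SD undefined for trait '", trait, "'")
  if (s == 0)
    warning("ancestor SD is 0 for trait '", trait,
            "': bounds degenerate, any deviating line is flagged")
  vals <- unlist(lapply(groups, function(g) lv[[g]]), use.names = TRUE)
  grp <- rep(groups, times = vapply(groups, function(g) length(lv[[g]]), 0L))
  z <- if (s > 0) (vals - m) / s else ifelse(vals == m, 0, Inf * sign(vals - m))
  dir <- ifelse(z < -cutoff, "low", ifelse(z > cutoff, "high", "none"))
  list(bounds = c(lower = m - cutoff * s, upper = m + cutoff * s),
       ancestor_mean = m, ancestor_sd = s, cutoff = cutoff,
       calls = data.frame(line_id = names(vals), group = grp,
                          trait = trait, value = unname(vals),
                          z_score = unname(z), direction = unname(dir),
                          stringsAsFactors = FALSE))
}

#' Adjust p values for multiple comparisons
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the two corrections
#' used in the pipeline.
#'
#' @param p numeric vector of p values.
#' @param method `"benjamini_hochberg"` (default) or `"bonferroni"`.
#' @param n family size (defaults to `length(p)`).
#' @return adjusted p values, clipped at 1.
#' @export
adjust_pvalues <- function(p, method = c("benjamini_hochberg", "bonferroni"),
                           n = length(p)) {
  method <- match.arg(method)
  p.adjust(p, method = if (method == "bonferroni") "bonferroni" else "BH",
           n = n)
}
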