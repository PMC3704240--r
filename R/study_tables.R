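#' Published summary tables of the reference MA experiment
#'
#' Loads the printed summary statistics of the 90-line, 994-generation
#' mutation-accumulation experiment in *Dictyostelium discoideum* that the
#' package's methods are built around: per-group trait means and variances,
#' per-line significance-call counts with their confidence bounds, the
#' pairwise Spearman correlation matrix among the eight fitness components,
#' the observed and simulation-expected distribution of affected components
#' per line, and the published maximum-likelihood and Bateman-Mukai
#' parameter estimates with support bounds (`Inf` marks an open interval
#' end). These tables are inputs for reanalysis -- the raw per-line trait
#' values were not deposited.
#'
#' @return list with elements `group_summaries`, `line_calls`,
#'   `correlations` (8 x 8 matrix), `affected_counts`, `ml_estimates`,
#'   `bm_estimates`, and `G = 994`.
#' @export
dicty_ma_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "mafitkit",
                                  mustWork = TRUE)
  corr <- read.csv(path("dicty_ma_trait_correlations.csv"),
                   row.names = 1, check.names = FALSE)
  list(group_summaries = read.csv(path("dicty_ma_group_summaries.csv"),
                                  stringsAsFactors = FALSE),
       line_calls = read.csv(path("dicty_ma_line_calls.csv"),
                             stringsAsFactors = FALSE),
       correlations = as.matrix(corr),
       affected_counts = read.csv(path("dicty_ma_affected_counts.csv")),
       ml_estimates = read.csv(path("dicty_ma_ml_estimates.csv"),
                               stringsAsFactors = FALSE),
       bm_estimates = read.csv(path("dicty_ma_bm_estimates.csv"),
                               stringsAsFactors = FALSE),
       G = 994)
}

#' Genome-wide mutation-rate bound from per-component support bounds
#'
#' Sums the lower support bounds of the per-component mutation rates to a
#' lower bound on the genome-wide rate of fitness-altering mutations, and
#' reports the mean lower bound over a chosen subset of components.
#'
#' @param ml_estimates data frame with columns `trait` and `U_lo` (as in
#'   `dicty_ma_tables()$ml_estimates`).
#' @param mean_exclude traits excluded from the mean (default
#'   `"plate_growth"`, whose bound is depressed by selection during
#'   accumulation).
#' @return list with `sum_lower` (per generation), `mean_lower` over the
#'   included components, and `n_components` used in the sum.
#' @export
total_mutation_rate_bound <- function(ml_estimates,
                                      mean_exclude = "plate_growth") {
  lo <- ml_estimates$U_lo
  keep <- !is.na(lo)
  inc <- keep & !(ml_estimates$trait %in% mean_exclude)
  list(sum_lower = sum(lo[keep]), mean_lower = mean(lo[inc]),
       n_components = sum(keep))
}
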