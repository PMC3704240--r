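#' Run the full MA analysis pipeline
#'
#' Orchestrates the analysis stages on a replicate-level fitness table:
#' relative-fitness normalisation, group summaries with nonparametric mean
#' (Wilcoxon) and variance (rank Levene) comparisons, per-line significance
#' calls against Bonferroni-corrected ancestor bounds, Bateman-Mukai
#' estimates, pleiotropy diagnostics (Spearman matrix, effective number of
#' traits, Poisson-binomial null, both randomization tests), and optionally
#' the maximum-likelihood fits (the slow stage, off by default). The run is
#' deterministic given `seed`.
#'
#' @param table a [fitness_table()] (raw or already relative scale).
#' @param alpha familywise level for per-line calls (default 0.05).
#' @param family_size Bonferroni family for the per-line cutoff; `"auto"`
#'   uses the number of tested (MA + control) lines.
#' @param n_sims randomizations per pleiotropy test.
#' @param seed master seed for all randomness.
#' @param ml run [fit_ml()] per trait (slow).
#' @param ml_settings settings for the ML stage.
#' @param normalise apply [relative_fitness()] first.
#' @param out_dir optional directory; JSON reports are written per stage.
#' @return list of class `ma_report` with elements `summaries`,
#'   `mean_tests`, `var_tests`, `classification`, `bm`, `pleiotropy`,
#'   `ml` (or `NULL`), `seed`, `alpha`, `cutoff`.
#' @export
run_ma_pipeline <- function(table, alpha = 0.05, family_size = "auto",
                            n_sims = 1000, seed = 1, ml = FALSE,
                            ml_settings = mafitkit::ml_settings(),
                            normalise = TRUE, out_dir = NULL) {
  set.seed(seed)
  if (normalise) table <- relative_fitness(table)
  traits <- unique(table$trait)
  n_tested <- length(unique(table$line_id[table$group != "ancestor"]))
  fam <- if (identical(family_size, "auto")) n_tested else family_size
  cutoff <- bonferroni_cutoff(alpha, fam)

  summaries <- summarize_fitness(table)

  # group comparisons per trait: MA vs ancestor means and variances
  mean_tests <- do.call(rbind, lapply(traits, function(tr) {
    lv <- line_values(table, tr)
    wt <- wilcoxon_rank_sum(lv$MA, lv$ancestor)
    data.frame(trait = tr, test = "wilcoxon_MA_vs_ancestor",
               statistic = wt$statistic, p_value = wt$p_value)
  }))
  mean_tests$adjusted_p <- adjust_pvalues(mean_tests$p_value)
  var_tests <- do.call(rbind, lapply(traits, function(tr) {
    lv <- line_values(table, tr)
    vals <- c(lv$ancestor, lv$control, lv$MA)
    grp <- rep(c("ancestor", "control", "MA"),
               c(length(lv$ancestor), length(lv$control), length(lv$MA)))
    lt <- rank_levene(vals, grp)
    data.frame(trait = tr, test = "rank_levene_three_group",
               statistic = lt$statistic, p_value = lt$p_value)
  }))
  var_tests$adjusted_p <- adjust_pvalues(var_tests$p_value)

  classification <- lapply(traits, function(tr)
    classify_lines(table, tr, cutoff = cutoff))
  names(classification) <- traits
  class_table <- do.call(rbind, lapply(traits, function(tr) {
    cl <- classification[[tr]]
    ma <- cl$calls[cl$calls$group == "MA", ]
    data.frame(trait = tr, lower_ci = cl$bounds["lower"],
               upper_ci = cl$bounds["upper"],
               low_lines = sum(ma$direction == "low"),
               high_lines = sum(ma$direction == "high"),
               row.names = NULL)
  }))

  bm <- bm_estimate_all(table)

  # pleiotropy stage
  ltm <- line_trait_matrix(table)
  pleio <- NULL
  if (ncol(ltm) >= 2 && nrow(ltm) >= 4) {
    sp <- spearman_matrix(ltm)
    eff <- if (!any(sp$constant)) effective_traits(sp$r) else NULL
    calls <- sapply(traits, function(tr) {
      cl <- classification[[tr]]$calls
      cl <- cl[cl$group == "MA", ]
      setNames(cl$direction != "none", cl$line_id)[rownames(ltm)]
    })
    k_sig <- colSums(calls)
    n_lines <- nrow(calls)
    rates <- lapply(traits, function(tr)
      if (k_sig[tr] < n_lines)
        component_rate(k_sig[tr], n_lines, attr(table, "G"), trait = tr)
      else NULL)
    lambda <- vapply(rates, function(r) if (is.null(r)) NA_real_
                     else r$lambda_hat, numeric(1))
    obs_cat <- tally_categories(rowSums(calls), length(traits))
    randA <- randomization_test_A(calls, n_sims = n_sims, seed = seed)
    randB <- if (!any(is.na(lambda)))
      randomization_test_B(lambda, obs_cat, n_lines, n_sims = n_sims,
                           seed = seed + 1) else NULL
    pleio <- list(spearman = sp, effective_traits = eff,
                  k_sig = k_sig, lambda = lambda,
                  expected = expected_affected_distribution(k_sig / n_lines,
                                                            n_lines),
                  randomization_A = randA, randomization_B = randB)
  }

  ml_fits <- NULL
  if (ml) {
    ml_fits <- lapply(traits, function(tr) {
      lv <- line_values(table, tr)
      tryCatch(fit_ml(lv$ancestor, unname(lv$MA), G = attr(table, "G"),
                      settings = ml_settings),
               error = function(e) {
                 warning("ML stage failed for trait '", tr, "': ",
                         conditionMessage(e))
                 NULL
               })
    })
    names(ml_fits) <- traits
  }

  report <- structure(list(summaries = summaries, mean_tests = mean_tests,
                           var_tests = var_tests,
                           classification = class_table,
                           classification_detail = classification,
                           bm = bm, pleiotropy = pleio, ml = ml_fits,
                           seed = seed, alpha = alpha, cutoff = cutoff,
                           G = attr(table, "G")),
                      class = "ma_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wj <- function(x, f) jsonlite::write_json(
      x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA,
      force = TRUE, na = "null")
    wj(summaries, "group_summaries.json")
    wj(class_table, "line_classification.json")
    wj(bm, "bateman_mukai.json")
    if (!is.null(pleio))
      wj(list(n_eff = pleio$effective_traits$n_eff,
              k_sig = as.list(pleio$k_sig),
              expected = pleio$expected,
              randomization_A = pleio$randomization_A[
                c("chi2", "df", "p", "significant_fraction")],
              randomization_B = if (is.null(pleio$randomization_B)) NULL
              else pleio$randomization_B[
                c("chi2", "df", "p", "significant_fraction")]),
         "pleiotropy.json")
    wj(list(seed = seed, alpha = alpha, cutoff = cutoff, G = report$G,
            n_sims = n_sims), "run_config.json")
  }
  report
}

#' @export
print.ma_report <- function(x, ...) {
  cat("MA analysis report (seed ", x$seed, ", cutoff ",
      sprintf("%.3f", x$cutoff), " SD)\n\n", sep = "")
  cat("Per-line classification:\n")
  print(x$classification, row.names = FALSE)
  cat("\nBateman-Mukai estimates:\n")
  print(x$bm[c("trait", "applicable", "E_a", "U_per_gen")],
        row.names = FALSE)
  if (!is.null(x$pleiotropy) && !is.null(x$pleiotropy$effective_traits))
    cat(sprintf("\nEffective number of traits: %.2f\n",
                x$pleiotropy$effective_traits$n_eff))
  invisible(x)
}
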