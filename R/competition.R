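#' Competitive-ability index from a labelled-spore assay
#'
#' The ratio of line to ancestor spores divided by the ratio of line to
#' ancestor cells in the initial mix:
#' `C = (S_line/S_anc) / (N_line/N_anc)`. Values below 1 indicate a poorer
#' competitor than the ancestor, above 1 a better one. The index is scale
#' invariant in all four counts.
#'
#' @param S_line,S_anc spore counts attributed to line and ancestor.
#' @param N_line,N_anc initial cell counts of line and ancestor.
#' @return the index, or `NA` (with a warning) when `S_anc = 0` leaves it
#'   undefined.
#' @export
competition_index <- function(S_line, S_anc, N_line, N_anc) {
  if (any(c(S_line, S_anc, N_line, N_anc) < 0)) stop("counts must be >= 0")
  if (N_anc <= 0 || N_line <= 0) stop("initial cell counts must be > 0")
  if (S_anc == 0) {
    warning("no ancestor spores scored: index undefined")
    return(NA_real_)
  }
  (S_line / S_anc) / (N_line / N_anc)
}

#' Aggregate the two reciprocal competition mixes
#'
#' Line-level competitive ability is the arithmetic mean of the indices
#' from the two reciprocally labelled mixes; with one mix missing the other
#' is returned and flagged.
#'
#' @param a index from the mix with the line labelled.
#' @param b index from the mix with the ancestor labelled.
#' @return list with `index` and `coverage` ("both" or "single").
#' @export
aggregate_reciprocal <- function(a, b) {
  ok <- c(!is.na(a), !is.na(b))
  if (!any(ok)) return(list(index = NA_real_, coverage = "none"))
  if (all(ok)) list(index = (a + b) / 2, coverage = "both")
  else list(index = c(a, b)[ok], coverage = "single")
}

#' Compute per-line competitive ability from assay count records
#'
#' Takes assay rows with columns `line_id`, `labeled_strain` ("line" or
#' "ancestor"), `n_cells_labeled`, `n_cells_total`, `n_spores_labeled`,
#' `n_spores_total`, converts labelled fractions to strain counts (the
#' labelled strain's spores are the labelled spores; optionally corrected
#' for dye retention), computes the index per mix and averages the
#' reciprocal mixes per line.
#'
#' @param assays data frame of assay records (e.g. rbind of
#'   [simulate_competition_counts()] outputs).
#' @param retention_correction divide the labelled fraction by this dye
#'   retention rate before attribution (default 1, no correction).
#' @return data frame with `line_id`, `index`, `coverage`; rows compatible
#'   with [fitness_table()] via trait `competitive_ability`.
#' @export
competition_table <- function(assays, retention_correction = 1) {
  one_mix <- function(row) {
    lf_cells <- row$n_cells_labeled / row$n_cells_total
    lf_spores <- min(row$n_spores_labeled / row$n_spores_total /
                       retention_correction, 1)
    S_lab <- lf_spores * row$n_spores_total
    S_unlab <- row$n_spores_total - S_lab
    N_lab <- lf_cells * row$n_cells_total
    N_unlab <- row$n_cells_total - N_lab
    if (row$labeled_strain == "line")
      competition_index(S_lab, S_unlab, N_lab, N_unlab)
    else
      competition_index(S_unlab, S_lab, N_unlab, N_lab)
  }
  out <- lapply(split(assays, assays$line_id), function(d) {
    ca <- cb <- NA_real_
    for (i in seq_len(nrow(d))) {
      v <- one_mix(d[i, ])
      if (d$labeled_strain[i] == "line") ca <- v else cb <- v
    }
    agg <- aggregate_reciprocal(ca, cb)
    data.frame(line_id = d$line_id[1], index = agg$index,
               coverage = agg$coverage, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
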