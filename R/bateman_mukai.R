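#' Bateman-Mukai moment estimates of mutational parameters
#'
#' Uses the decline in mean relative fitness of MA lines and the inflation
#' of the among-line variance over the accumulation phase:
#' `dM = mean_ancestor - mean_MA`, `dV = var_MA - var_ancestor`,
#' `E(a) = dV/dM` and `U = (dM^2/dV)/G`. The method assumes all mutations
#' are deleterious with equal effects; with variable effects it
#' underestimates `U` and overestimates `E(a)`.
#'
#' The estimate is withheld (with a reason code) unless `dM > 0`, `dV > 0`
#' and `dM > dV`; the last condition is the applicability screen used when
#' the variance response exceeds the mean response.
#'
#' @param ancestor,ma either group summary rows (lists/one-row data frames
#'   with `mean` and `var`) or raw numeric vectors of relative-fitness
#'   values (ancestor replicates; MA line means).
#' @param G generations of accumulation (default 994).
#' @param trait optional trait label carried into the result.
#' @return object of class `bm_estimate`: `trait`, `delta_M`, `delta_V`,
#'   `applicable`, and when applicable `E_a` and `U_per_gen` (else `NA` with
#'   `reason`).
#' @export
bm_estimate <- function(ancestor, ma, G = 994, trait = NA_character_) {
  as_summ <- function(x) {
    if (is.numeric(x)) list(mean = mean(x), var = var(x))
    else list(mean = x$mean[1], var = x$var[1])
  }
  anc <- as_summ(ancestor); maa <- as_summ(ma)
  dM <- anc$mean - maa$mean
  dV <- maa$var - anc$var
  reason <- NULL
  if (!(dM > 0)) reason <- c(reason, "no mean decline (dM <= 0)")
  if (!(dV > 0)) reason <- c(reason, "no variance inflation (dV <= 0)")
  if (dM > 0 && dV > 0 && !(dM > dV))
    reason <- c(reason, "variance response exceeds mean response (dM <= dV)")
  applicable <- is.null(reason)
  structure(list(trait = trait, delta_M = dM, delta_V = dV,
                 applicable = applicable,
                 E_a = if (applicable) dV / dM else NA_real_,
                 U_per_gen = if (applicable) (dM^2 / dV) / G else NA_real_,
                 G = G,
                 reason = if (applicable) NA_character_
                          else paste(reason, collapse = "; ")),
            class = "bm_estimate")
}

#' @export
print.bm_estimate <- function(x, ...) {
  if (x$applicable) {
    cat(sprintf("Bateman-Mukai%s: dM = %.4g, dV = %.4g -> E(a) = %.4g, U = %.4g per generation (G = %d)\n",
                if (is.na(x$trait)) "" else paste0(" [", x$trait, "]"),
                x$delta_M, x$delta_V, x$E_a, x$U_per_gen, x$G))
  } else {
    cat(sprintf("Bateman-Mukai%s: not applicable (%s)\n",
                if (is.na(x$trait)) "" else paste0(" [", x$trait, "]"),
                x$reason))
  }
  invisible(x)
}

#' Bateman-Mukai estimates for every trait of a fitness table
#'
#' @param table a [fitness_table()] on the relative scale.
#' @param G generations; defaults to the table's `G` attribute.
#' @return data frame with one row per trait: delta_M, delta_V, applicable,
#'   E_a, U_per_gen, reason.
#' @export
bm_estimate_all <- function(table, G = attr(table, "G")) {
  traits <- unique(table$trait)
  rows <- lapply(traits, function(tr) {
    lv <- line_values(table, tr)
    est <- bm_estimate(lv$ancestor, unname(lv$MA), G = G, trait = tr)
    data.frame(trait = tr, delta_M = est$delta_M, delta_V = est$delta_V,
               applicable = est$applicable, E_a = est$E_a,
               U_per_gen = est$U_per_gen, reason = est$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
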