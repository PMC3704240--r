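#' Mutational model parameters for one trait
#'
#' Bundle of generative/inferential parameters: `U`, the per-haploid-genome
#' per-generation rate of mutations altering the trait; `G`, generations of
#' accumulation; `P`, the fraction of mutations with beneficial (positive)
#' effect; gamma effect-magnitude distribution with shape `beta` and rate
#' `alpha` (mean effect `E(a) = beta/alpha`), reflected around zero with
#' sign + with probability `P`; and `sigma_env`, the assay-error SD on the
#' relative-fitness scale. `M = U * G` is the expected number of mutations
#' per line.
#'
#' @param U mutation rate per haploid genome per generation (>= 0).
#' @param G generations (default 994).
#' @param P beneficial fraction in `[0, 1]`.
#' @param alpha gamma rate parameter (> 0).
#' @param beta gamma shape parameter (> 0).
#' @param sigma_env assay error SD (> 0).
#' @return object of class `ma_params`.
#' @export
ma_params <- function(U, G = 994, P = 0, alpha = 10, beta = 1,
                      sigma_env = 0.03) {
  vals <- c(U = U, G = G, P = P, alpha = alpha, beta = beta,
            sigma_env = sigma_env)
  if (any(!is.finite(vals))) stop("non-finite parameter in ma_params")
  if (U < 0) stop("U must be >= 0")
  if (P < 0 || P > 1) stop("P must lie in [0, 1]")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  if (sigma_env <= 0) stop("sigma_env must be > 0")
  structure(list(U = U, G = G, P = P, alpha = alpha, beta = beta,
                 sigma_env = sigma_env, M = U * G,
                 E_a = beta / alpha),
            class = "ma_params")
}

#' @export
print.ma_params <- function(x, ...) {
  cat(sprintf(
    "ma_params: U = %.4g (M = U*G = %.3g), G = %d, P = %.2f, E(a) = beta/alpha = %.4g (beta = %.3g), sigma_env = %.4g\n",
    x$U, x$M, x$G, x$P, x$E_a, x$beta, x$sigma_env))
  invisible(x)
}

#' Experimental design for the synthetic generator
#'
#' Defaults reproduce the reference design: 90 MA lines, 10 control lines,
#' per-trait ancestor replicate counts between 9 and 42, and per-line
#' replicate counts following the assay protocols (5 plaques for plate
#' growth, 2 germination plates of 100 spores, 2 reciprocal competition
#' mixes, single assays otherwise). `control_retention` (kappa) scales the
#' effective mutational input of control lines, summarising their larger
#' effective population size phenomenologically.
#'
#' @param n_ma number of MA lines.
#' @param n_control number of control lines.
#' @param ancestor_reps named integer vector, ancestor replicates per trait.
#' @param reps_per_line named integer vector, replicates per MA/control line.
#' @param control_retention kappa in `[0, 1]`.
#' @return object of class `ma_design`.
#' @export
ma_design <- function(n_ma = 90, n_control = 10,
                      ancestor_reps = c(plate_growth = 16, liquid_growth = 16,
                                        slug_distance = 12, total_fbs = 9,
                                        spores_per_fb = 12, total_spores = 12,
                                        spore_germination = 17,
                                        competitive_ability = 42),
                      reps_per_line = c(plate_growth = 5, liquid_growth = 1,
                                        slug_distance = 1, total_fbs = 1,
                                        spores_per_fb = 1, total_spores = 1,
                                        spore_germination = 2,
                                        competitive_ability = 2),
                      control_retention = 0.1) {
  if (n_ma < 1 || n_control < 0) stop("counts must be positive")
  if (any(ancestor_reps < 1) || any(reps_per_line < 1))
    stop("replicate counts must be positive")
  if (control_retention < 0 || control_retention > 1)
    stop("control_retention must lie in [0, 1]")
  structure(list(n_ma = n_ma, n_control = n_control,
                 ancestor_reps = ancestor_reps,
                 reps_per_line = reps_per_line,
                 control_retention = control_retention),
            class = "ma_design")
}

# draw compound-Poisson reflected-gamma mutational shifts for n lines;
# returns list(shift, counts, effects) -- effects is a list per line
draw_line_shifts <- function(n, par) {
  k <- rpois(n, par$M)
  effects <- lapply(k, function(ki) {
    if (ki == 0) return(numeric(0))
    mag <- rgamma(ki, shape = par$beta, rate = par$alpha)
    sgn <- ifelse(runif(ki) < par$P, 1, -1)
    mag * sgn
  })
  list(shift = vapply(effects, sum, numeric(1)), counts = k,
       effects = effects)
}

#' Simulate a mutation-accumulation experiment
#'
#' For each line and trait, draws a Poisson number of mutations with mean
#' `U*G`; each mutation's effect is `+|a|` with probability `P` and `-|a|`
#' otherwise, `|a| ~ Gamma(shape = beta, rate = alpha)`. The line's true
#' relative fitness is `1 + sum(effects)` (additive on the relative scale)
#' and each assay replicate adds `Normal(0, sigma_env)` error. Traits mutate
#' independently (no pleiotropy). Control lines receive mutational input
#' `U * control_retention`. Ancestor replicates are mutation-free.
#'
#' For `spore_germination` the true rate is truncated into `[0, 1]` and
#' replicates are generated as binomial germination counts out of
#' `spores_per_plate` (see [simulate_germination_counts()]), keeping the
#' emitted schema identical to real data.
#'
#' @param params a single [ma_params()] (applied to all traits) or a named
#'   list of per-trait [ma_params()].
#' @param design an [ma_design()].
#' @param traits traits to simulate (default: names of `params` if a list,
#'   else all eight).
#' @param multiplicative combine effects as `prod(1 + a)` instead of the
#'   default `1 + sum(a)` (robustness variant, off by default).
#' @param seed optional integer seed (set once for the whole table).
#' @param spores_per_plate binomial denominator for germination replicates.
#' @return a [fitness_table()] on the relative-fitness scale, with a `truth`
#'   attribute: per-trait list of per-line mutation `counts`, `effects` and
#'   true line values.
#' @export
simulate_ma_experiment <- function(params, design = ma_design(),
                                   traits = NULL, multiplicative = FALSE,
                                   seed = NULL, spores_per_plate = 100) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "ma_params")) {
    if (is.null(traits)) traits <- .ma_traits
    params <- setNames(rep(list(params), length(traits)), traits)
  } else {
    if (is.null(traits)) traits <- names(params)
    stopifnot(all(traits %in% names(params)))
  }
  G <- params[[1]]$G
  recs <- list(); truth <- list()
  ma_ids <- sprintf("MA%02d", seq_len(design$n_ma))
  ct_ids <- if (design$n_control > 0) sprintf("C%02d", seq_len(design$n_control)) else character(0)

  for (tr in traits) {
    par <- params[[tr]]
    kappa <- design$control_retention
    par_ct <- ma_params(U = par$U * kappa, G = par$G, P = par$P,
                        alpha = par$alpha, beta = par$beta,
                        sigma_env = par$sigma_env)
    n_anc <- unname(design$ancestor_reps[tr])
    if (is.na(n_anc)) n_anc <- 12
    r <- unname(design$reps_per_line[tr])
    if (is.na(r)) r <- 1

    ma <- draw_line_shifts(design$n_ma, par)
    ct <- if (design$n_control > 0) draw_line_shifts(design$n_control, par_ct)
          else list(shift = numeric(0), counts = integer(0), effects = list())
    true_val <- function(d) {
      if (!multiplicative) 1 + d$shift
      else vapply(d$effects, function(e) prod(1 + e), numeric(1))
    }
    ma_true <- true_val(ma); ct_true <- true_val(ct)

    emit <- function(ids, true, group) {
      if (!length(ids)) return(NULL)
      if (tr == "spore_germination") {
        true <- pmin(pmax(true, 0), 1)
        do.call(rbind, lapply(seq_along(ids), function(i) {
          cnt <- simulate_germination_counts(true[i], plates = r,
                                             spores_per_plate = spores_per_plate)
          data.frame(line_id = ids[i], group = group, trait = tr,
                     block = NA_integer_, replicate = seq_len(r),
                     value = cnt / spores_per_plate,
                     stringsAsFactors = FALSE)
        }))
      } else {
        data.frame(line_id = rep(ids, each = r), group = group, trait = tr,
                   block = NA_integer_,
                   replicate = rep(seq_len(r), length(ids)),
                   value = rep(true, each = r) +
                     rnorm(length(ids) * r, 0, par$sigma_env),
                   stringsAsFactors = FALSE)
      }
    }
    anc_rec <- if (tr == "spore_germination") {
      cnt <- simulate_germination_counts(1, plates = n_anc,
                                         spores_per_plate = spores_per_plate)
      data.frame(line_id = "ANC", group = "ancestor", trait = tr,
                 block = NA_integer_, replicate = seq_len(n_anc),
                 value = cnt / spores_per_plate, stringsAsFactors = FALSE)
    } else {
      data.frame(line_id = "ANC", group = "ancestor", trait = tr,
                 block = NA_integer_, replicate = seq_len(n_anc),
                 value = 1 + rnorm(n_anc, 0, par$sigma_env),
                 stringsAsFactors = FALSE)
    }
    recs[[tr]] <- rbind(anc_rec, emit(ct_ids, ct_true, "control"),
                        emit(ma_ids, ma_true, "MA"))
    truth[[tr]] <- list(ma_counts = setNames(ma$counts, ma_ids),
                        ma_effects = setNames(ma$effects, ma_ids),
                        ma_true = setNames(ma_true, ma_ids),
                        control_counts = setNames(ct$counts, ct_ids),
                        control_true = setNames(ct_true, ct_ids))
  }
  tab <- fitness_table(do.call(rbind, recs), G = G)
  attr(tab, "truth") <- truth
  tab
}

#' Simulate germination counts
#'
#' Binomial germination counts per plate at a true germination rate.
#'
#' @param line_true_rate true germination probability in `[0, 1]`.
#' @param plates number of plates.
#' @param spores_per_plate spores plated per plate.
#' @return integer vector of germinated-spore counts, one per plate.
#' @export
simulate_germination_counts <- function(line_true_rate, plates = 2,
                                        spores_per_plate = 100) {
  if (!is.finite(line_true_rate) || line_true_rate < 0 || line_true_rate > 1)
    stop("germination rate must lie in [0, 1]")
  if (plates < 1 || spores_per_plate < 1) stop("counts must be >= 1")
  rbinom(plates, spores_per_plate, line_true_rate)
}

#' Simulate a labelled-spore competition assay
#'
#' Generates both reciprocal mixes of a line against the ancestor. The
#' initial labelled-cell fraction among `n_scored_cells` scored cells is
#' binomial around the nominal mix fraction; the labelled-spore fraction
#' among `n_scored_spores` scored spores is binomial around the fraction
#' implied by the line's true competitive index (odds `true_index` to 1 at
#' an equal mix). Optionally a fraction `1 - retention` of labelled spores
#' loses the dye and is scored unlabelled.
#'
#' @param true_index true competitive index (> 0); 1 is neutral.
#' @param n_scored_cells cells scored in the initial mix (>= 1).
#' @param n_scored_spores spores scored after fruiting (>= 1).
#' @param mix_fraction nominal initial fraction of the labelled strain.
#' @param retention labelled-spore dye retention (default 1, no loss; the
#'   assay's measured retention was 0.992).
#' @param line_id line identifier carried into the output.
#' @return data frame of class `competition_assay`, two rows (line labelled,
#'   ancestor labelled) with scored counts.
#' @export
simulate_competition_counts <- function(true_index, n_scored_cells = 500,
                                        n_scored_spores = 500,
                                        mix_fraction = 0.5, retention = 1,
                                        line_id = "line") {
  if (!is.finite(true_index) || true_index <= 0)
    stop("true_index must be > 0")
  if (n_scored_cells < 1 || n_scored_spores < 1)
    stop("scored counts must be >= 1")
  one_mix <- function(labeled) {
    lab_cells <- rbinom(1, n_scored_cells, mix_fraction)
    lab_cells <- max(1, min(n_scored_cells - 1, lab_cells))
    frac_cells <- lab_cells / n_scored_cells
    # spore odds = cell odds of the focal strain scaled by its index
    odds <- if (labeled == "line") {
      true_index * frac_cells / (1 - frac_cells)
    } else {
      (frac_cells / (1 - frac_cells)) / true_index
    }
    p_spore <- odds / (1 + odds)
    lab_spores <- rbinom(1, n_scored_spores, p_spore)
    if (retention < 1) lab_spores <- rbinom(1, lab_spores, retention)
    data.frame(line_id = line_id, labeled_strain = labeled,
               n_cells_labeled = lab_cells, n_cells_total = n_scored_cells,
               n_spores_labeled = lab_spores, n_spores_total = n_scored_spores,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_mix("line"), one_mix("ancestor"))
  class(out) <- c("competition_assay", "data.frame")
  out
}
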