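---
title: "Estimating mutational parameters from mutation-accumulation fitness assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutational parameters from mutation-accumulation fitness assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mafitkit)
```

`mafitkit` implements the statistical pipeline of a mutation-accumulation
(MA) experiment on quantitative fitness components, following the design of
a 90-MA-line, 10-control-line, 994-cell-generation experiment in
*Dictyostelium discoideum* with eight assayed fitness components. This
vignette records the models, the numerical choices, and the reasoning
behind the design decisions that were genuinely open, so that a maintainer
can tell deliberate behaviour from accident.

## Data model and normalisation

The universal currency is the `fitness_table`: a long-format table of
replicate-level measurements with columns `line_id`, `group`
(ancestor/control/MA), `trait`, `block`, `replicate`, `value`, carrying the
generation count `G` as metadata. All inference happens on *relative
fitness*: each value divided by the ancestor mean for its trait, so the
ancestor mean is exactly 1 by construction.

Two normalisation choices deserve note:

* **Blocks are pooled before normalising.** Assays run in multiple blocks
  always included ancestor replicates per block; block homogeneity is
  screened with a Kruskal–Wallis test (`kruskal_wallis_blocks`, df =
  blocks − 1) and, when non-significant, all blocks are combined. A
  per-block normalisation mode exists (`relative_fitness(per_block =
  TRUE)`) but is off by default, because per-block ancestor means computed
  from few replicates add noise to every line's value.
* **MA and control lines enter group statistics as line means** (replicates
  averaged within line first); the ancestor enters as individual
  replicates. Sample variances use divisor n − 1 throughout, and a group
  with a single value reports variance `NA`, never a spurious 0.

Replicate outliers are screened once (no iteration) by flagging values more
than 4 SD from the mean of their set, with the candidate included in the
mean/SD — a deliberate single-pass rule that cannot cascade.

## Group comparisons

The MA-line distributions are typically non-normal, so group comparisons
are rank-based:

* `wilcoxon_rank_sum` — two-sided rank-sum test with midranks for ties.
  For combined n ≤ 20 the null distribution is enumerated exactly over all
  splits (remaining exact under ties); beyond that a tie-corrected normal
  approximation with continuity correction is used. The two-sided p is
  `2 * min(P(S ≤ W), P(S ≥ W))` capped at 1.
* `rank_levene` — variance comparison: values are centred by their group
  *median*, pooled, converted to midranks, and a classical Levene ANOVA is
  run on absolute deviations of the ranks from their group rank means.
  Groups of constants produce zero deviations and a degenerate p = 1 flag,
  not an error.

Multiple comparisons across the eight-trait battery are corrected with
Benjamini–Hochberg by default (`adjust_pvalues`); Bonferroni is available.

## Per-line significance calls

Each line is compared with the ancestor distribution assuming normality:
bounds are `mean ± z·SD` with `z = bonferroni_cutoff(alpha, family)`, the
two-sided normal quantile at `alpha/family`. The default family is **all
tested lines** — 100 in the reference design (90 MA + 10 control), giving
z = 3.48 at α = 0.05. A family of 90 would give 3.45; the 100-line family
is the one consistent with the published 3.48 cutoff, and the family size
is a plain argument for users who prefer otherwise. The ancestor SD is the
pooled (all-block) SD.

## Bateman–Mukai estimators

With ΔM the ancestor-minus-MA mean difference and ΔV the MA-minus-ancestor
among-line variance difference on the relative scale,
`E(a) = ΔV/ΔM` and `U = (ΔM²/ΔV)/G`. The estimate is withheld unless
ΔM > 0, ΔV > 0 **and ΔM > ΔV**. The last condition compares quantities in
different units and is therefore not dimensionally meaningful, but it is
the operative applicability screen in this literature and reproduces
exactly which components get withheld in the reference analysis (plate
growth and competitive ability); we implement it literally rather than
inventing a rescaled criterion. The internal identity `U·G·E(a) = ΔM`
holds exactly whenever the estimate is reported.

Because Bateman–Mukai assumes equal effects, on gamma-distributed effects
it *underestimates* U and *overestimates* E(a); with shape β = 1 the
asymptotic factors are exactly 2 in each direction. The test suite asserts
this bias direction on synthetic data.

## The likelihood model and its numerics

The line-mean model: k ~ Poisson(M), M = U·G; each of the k mutations has
absolute effect |a| ~ Gamma(β, α) (mean E(a) = β/α), sign + with
probability P; effects add, so the line mean is
`z = 1 + Σ aᵢ + ε`, ε ~ N(0, σ²). Ancestor replicates are mutation-free
observations `N(1, σ²)` and enter the joint likelihood, so σ is estimated
jointly rather than plugged in (a plug-in comparison is trivial to run by
fixing σ at the ancestor SD).

**Density evaluation.** The distribution of `z − 1` is a compound Poisson
with reflected-gamma jumps convolved with a normal, whose characteristic
function is closed-form:

    φ(t) = exp( M·(P(1 − it/α)^{−β} + (1 − P)(1 + it/α)^{−β} − 1) − σ²t²/2 )

`line_loglik` inverts φ by FFT on a symmetric grid (4096 nodes by default,
half-width 12 SD of the summed effect plus the data range) and
interpolates at the observations. This is mathematically identical to the
familiar truncated sum over (k, j) with a quadrature convolution, but it
is exact in k (the mutation-free atom appears automatically with weight
e^{−M}), conserves total mass to machine precision — the normalisation
check `∫f = 1 ± 1e−4` is part of the acceptance suite — and costs one FFT
per likelihood evaluation, which is what makes full profile likelihoods
affordable on one CPU. The explicit (k, j) representation is retained in
two places where it is the natural form: `effect_sum_density` (the
gamma-difference density for fixed k, j, discretised by exact cell masses
so that shapes below 1 lose no probability), and the equal-effects model,
whose mixture-of-normals density uses the Poisson tail rule (smallest k
with upper-tail mass < 1e−10, capped at 60).

**Search strategy.** Following the grid-profile approach, the likelihood
is maximised over (log U, log α, log σ) by Nelder–Mead from three
deterministic moment-matched starts in every cell of a fixed grid of
β ∈ {0.1, 0.5, 1, 2, 3, 4, 6, 8, 10, 50} × P ∈ {0, 0.1, ..., 0.5} (60
cells), then the grid is refined once around the best cell (geometric-mean
β neighbours, P ± 0.05, allowing P > 0.5). Everything is deterministic
given settings.

**Support intervals.** 2-log-unit support intervals for U and E(a) come
from profile likelihoods: at each point of a log-spaced grid (augmented
with a finer local grid around the point estimate), the remaining free
parameters are re-maximised, warm-starting each optimisation from its
neighbour's optimum so the profile is smooth. Profiles are maximised not
only over (α, σ) but across every (β, P) cell whose own maximum lies
within 2.5 log-units of the global optimum — cells further down can never
re-enter the 2-unit band, so this is exact for the interval while keeping
the cost proportional to the number of competitive cells. Crossings are
located by linear interpolation between grid points; an endpoint that
reaches the search bound (U ∈ [1e−6, 1], E(a) ∈ [1e−5, 2] per generation
and relative-fitness units) is flagged *open* and printed as 0 or ∞. The
E(a) floor of 1e−5 is deliberately far below any resolvable effect so
that the bound never closes a genuine ridge artificially.

The flat high-U/small-effect ridge — many tiny mutations being
indistinguishable from fewer larger ones — is the expected failure mode of
such data; `fit_ml` reports it via the open upper-U flag (`ridge`), and on
data whose likelihood surface is flat in every direction the profile is
flagged flat with both ends open rather than silently reporting a point
estimate.

## Pleiotropy diagnostics

* `spearman_matrix` — pairwise Spearman correlations of line means with
  midranks, BH-adjusted p values, constant traits flagged rather than
  erroring.
* `effective_traits` — N_eff = N − Var(λ) over the eigenvalues of the
  correlation matrix. The eigenvalue mean is exactly 1, and Var(λ) uses
  divisor N (population variance) by default; divisor N − 1 is exposed and
  both round to the same headline value (7.73 vs 7.69) on the reference
  matrix.
* `component_rate` — per-component rate from the mutation-free fraction,
  `μ = 1 − ((n−k)/n)^{1/G}`, with λ = G·μ expected mutations per line; the
  inversion `(1−μ)^G·n = n − k` holds to 1e−9 by construction.
* `expected_affected_distribution` — the exact Poisson-binomial pmf of the
  number of affected components per line under independence, computed by
  iterated convolution; it is the analytic limit of both randomization
  tests and anchors them in the test suite.
* Randomization test A reshuffles each trait's observed significant calls
  across lines; test B draws per-line, per-component Poisson mutation
  counts at the λ̂ point estimates. Each simulated dataset's category
  counts (0–8 affected components) serve as the expectation in a χ²
  comparison against the observed counts, with df = 8 over all nine
  categories and **zero-expectation categories excluded from the sum**.
  The exclusion rule matters: a simulated zero count in a category where a
  line was observed would otherwise force χ² = ∞ and reject in the
  majority of simulations, which is incompatible with the reference
  behaviour of ~7% significant simulations; excluding empty cells
  reproduces it. A pooled-cell variant was considered and rejected because
  the reference df of 8 implies unpooled categories.
* `adhoc_lower_bound_U` — the "no mutation-free line was seen" bound. The
  verbal statement ("the rate at which the probability of obtaining zero
  no-mutation lines in 90 lines is less than 5%") admits two readings,
  `(1 − e^{−UG})^{90}` equal to 0.05 or to 0.95, giving UG ≈ 3.42 or 7.47
  (U ≈ 0.0034 or 0.0075). Neither reproduces the published 0.01 exactly;
  both are returned, labelled, and none is forced to match.
* `cubic_optimum` — the stabilizing-selection screen: least-squares cubic
  of a fitness proxy on a component, an F-test of the nonlinear terms
  against the linear fit, and the interior local maximum of the fitted
  cubic if one exists (absent is a result, not an error).

## The synthetic generator

`simulate_ma_experiment` emulates the reference design: 90 MA lines, 10
control lines, per-trait ancestor replicate counts of 9–42, G = 994,
per-line replicate counts following the assay protocols (5 plaques for
plate growth, 2 germination plates of 100 spores, 2 reciprocal competition
mixes, single assays otherwise). Per line and trait, k ~ Poisson(U·G)
reflected-gamma effects add on the relative scale (`1 + Σa`; a
multiplicative variant `Π(1+a)` exists for robustness studies but is not
the default, matching the additive convolution structure of the
likelihood), replicates add N(0, σ) noise, and traits mutate
independently — the generator deliberately contains *no* pleiotropy, so
the pleiotropy tests run against a true null. Germination is generated as
binomial counts over plated spores and competition as labelled-cell and
labelled-spore counts (with an optional 99.2% dye-retention thinning), so
downstream code sees the same schema as real data. Default σ values are
calibrated to the published ancestor variances (e.g. 0.033 for liquid
growth, variance 0.0011).

Control lines are handled phenomenologically: their mutational input is
`U·κ` with a retention factor κ (default 0.1), summarising their larger
effective population size; the within-plate selection dynamics of the
control protocol are out of scope and no published value constrains κ, so
it should be treated as a scenario knob, not an estimate. With κ = 0
controls are statistically indistinguishable from ancestor replicates,
which the tests assert.

What the generator does **not** emulate: bottleneck population genetics
within transfers (drift and selection during the 14.2-generation growth
cycles), block effects, assay-specific error distributions beyond the
binomial/normal forms above, and any mutational correlation between
traits. Passing tests therefore validate the estimators under the model's
own assumptions — they do not certify robustness to, say, selection during
MA depressing plate-growth responses, which the reference analysis itself
flags as a caveat.

## Problem sizes and tolerances used by the test suite

Monte-Carlo checks use sizes chosen to keep each check's sampling error
well below the asserted tolerance: 4e4 lines for generator moment
identities, 2e5–1e6 draws for density oracles (compared on interval
probabilities within 4 binomial SEs), 1000–4000 randomization replicates,
and 20 seeded replicates at the full design size (n = 90, G = 994) for
parameter-recovery coverage of the support intervals (≥ 18/20 expected for
each of U and E(a)). ML fits in the recovery loop run at reduced numerical
settings (1024 FFT nodes, β ∈ {0.5, 1, 2}, P ∈ {0, 0.1, 0.3}, 21-point
profiles, no refinement) — the package's choice of a good
accuracy/runtime point for repeated fitting; single production fits
default to the full 60-cell grid with 4096 nodes. The ridge-detection
check generates U·G = 10 mutations of mean effect 0.002 against assay
noise 0.03 — effects an order of magnitude below per-assay resolution, the
regime the flat-ridge diagnostic exists for.

## Known limitations

* The raw per-line trait values of the reference experiment are not
  published; the bundled inputs are its printed summary tables. Bateman–
  Mukai cells and CI bounds are therefore recomputable only where the
  printed rounding permits: the published CI bounds for total spores
  (0.968, 1.032) are inconsistent with the published ancestor variance
  (0.0010 would give 0.890, 1.110), germination's variance prints as
  0.0000, and competitive ability reproduces only to ±0.004. These are
  discrepancies internal to the source tables, documented here rather than
  reconciled.
* Published ML point estimates cannot be reproduced without the raw data;
  the likelihood machinery is instead validated by construction — mass
  conservation, Monte-Carlo density oracles, parameter recovery with
  interval coverage, and ridge detection.
* `P` is a free mixture weight: on weakly informative data the (P, E(a))
  pair is only softly identified, which is visible as wide support
  intervals rather than hidden.
* The χ² zero-cell exclusion rule and the Bonferroni family of 100 are
  reconstructions of underdocumented choices in the reference analysis;
  both are explicit arguments/settings so alternatives are one keystroke
  away.
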