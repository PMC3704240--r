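Package: mafitkit
Title: Analysis of Mutation-Accumulation Experiments on Fitness Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mutation-accumulation (MA) experiments on
    quantitative fitness components, built around the design of a 90-line,
    994-generation MA experiment in the social amoeba Dictyostelium
    discoideum. Provides tidy ingestion of replicate-level trait tables,
    relative-fitness normalisation, nonparametric group comparisons
    (Wilcoxon rank-sum, median-centred rank Levene, Kruskal-Wallis block
    tests), per-line significance calling with Bonferroni-corrected normal
    bounds, Bateman-Mukai moment estimators of the genomic mutation rate and
    mean effect, full maximum-likelihood estimation under a compound-Poisson
    reflected-gamma model of mutational effects with profile-likelihood
    support intervals, pleiotropy diagnostics (Spearman correlation
    structure, effective number of traits from eigenvalue variance,
    Poisson-binomial nulls and randomization tests), a competitive-ability
    index for labelled-spore chimera assays, and a seeded synthetic-data
    generator reproducing the experimental design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
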