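# small in-code fixtures shared across test files

tiny_table <- function(anc = c(12, 12, 12), ma = list(L1 = c(10, 14), L2 = c(11, 13)),
                       trait = "liquid_growth", G = 994) {
  recs <- data.frame(line_id = "ANC", group = "ancestor", trait = trait,
                     block = NA_integer_, replicate = seq_along(anc),
                     value = anc, stringsAsFactors = FALSE)
  for (id in names(ma)) {
    recs <- rbind(recs, data.frame(line_id = id, group = "MA", trait = trait,
                                   block = NA_integer_,
                                   replicate = seq_along(ma[[id]]),
                                   value = ma[[id]], stringsAsFactors = FALSE))
  }
  fitness_table(recs, G = G)
}

# per-trait significant-line counts and observed affected-component
# distribution of the reference experiment (used as test inputs)
ref_k_sig <- c(plate_growth = 2, liquid_growth = 68, slug_distance = 48,
               total_fbs = 17, spores_per_fb = 43, total_spores = 77,
               spore_germination = 85, competitive_ability = 61)
ref_observed_categories <- c(0, 1, 4, 13, 24, 34, 11, 3, 0)
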