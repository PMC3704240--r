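trait,P_ml,P_lo,P_hi,Ea_ml,Ea_lo,Ea_hi,U_ml,U_lo,U_hi,note
plate_growth,0.3,0.03,0.70,0.112,0.022,0.150,0.0001,0.00003,0.0007,equal_effects_best
liquid_growth,0.15,0.03,0.46,0.11,0,0.135,0.0039,0.0024,Inf,
slug_distance,0.3,0.15,0.42,0,0,0.11,Inf,0.0050,Inf,
total_fbs,0.4,0.25,0.48,0.055,0,0.086,0.0027,0.0012,Inf,
spores_per_fb,0.4,0.25,0.42,0,0,0.12,Inf,0.0019,Inf,
total_spores,0,0,0.38,0.052,0,0.082,0.0026,0.0014,Inf,equal_effects_best
spore_germination,NA,NA,NA,NA,NA,NA,NA,NA,NA,poor_fit_abandoned
competitive_ability,0.3,0.22,0.46,0.23,0.08,0.26,0.0015,0.0014,0.0031,
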