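trait,Ea_bm,U_bm
plate_growth,NA,NA
liquid_growth,0.156,0.0019
slug_distance,0.206,0.0005
total_fbs,0.311,0.0002
spores_per_fb,0.338,0.0002
total_spores,0.053,0.0025
spore_germination,0.148,0.0033
competitive_ability,NA,NA
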