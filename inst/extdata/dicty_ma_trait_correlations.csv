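trait,plate_growth,liquid_growth,slug_distance,total_fbs,spores_per_fb,total_spores,spore_germination,competitive_ability
plate_growth,1.00,-0.03,-0.13,0.22,-0.08,0.06,-0.07,0.00
liquid_growth,-0.03,1.00,-0.06,-0.11,-0.04,-0.16,0.04,-0.09
slug_distance,-0.13,-0.06,1.00,0.17,-0.40,-0.26,0.11,-0.04
total_fbs,0.22,-0.11,0.17,1.00,-0.25,0.37,-0.02,-0.05
spores_per_fb,-0.08,-0.04,-0.40,-0.25,1.00,0.62,-0.15,0.02
total_spores,0.06,-0.16,-0.26,0.37,0.62,1.00,-0.23,-0.08
spore_germination,-0.07,0.04,0.11,-0.02,-0.15,-0.23,1.00,0.08
competitive_ability,0.00,-0.09,-0.04,-0.05,0.02,-0.08,0.08,1.00
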