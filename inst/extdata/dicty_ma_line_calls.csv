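trait,lower_ci,upper_ci,low_lines,high_lines
plate_growth,0.867,1.133,2,0
liquid_growth,0.886,1.114,67,1
slug_distance,0.858,1.142,42,6
total_fbs,0.871,1.129,14,3
spores_per_fb,0.858,1.142,35,8
total_spores,0.968,1.032,76,1
spore_germination,0.993,1.007,85,0
competitive_ability,0.911,1.089,44,17
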