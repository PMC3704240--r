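trait,group,n,mean,var
plate_growth,ancestor,16,1.000,0.0015
plate_growth,control,10,0.991,0.0011
plate_growth,MA,90,1.000,0.0025
liquid_growth,ancestor,16,1.000,0.0011
liquid_growth,control,10,0.922,0.0275
liquid_growth,MA,90,0.705,0.0471
slug_distance,ancestor,12,1.000,0.0017
slug_distance,control,10,0.867,0.0030
slug_distance,MA,90,0.889,0.0245
total_fbs,ancestor,9,1.000,0.0014
total_fbs,control,10,0.902,0.0016
total_fbs,MA,90,0.969,0.0112
spores_per_fb,ancestor,12,1.000,0.0017
spores_per_fb,control,10,1.033,0.0090
spores_per_fb,MA,90,0.919,0.0290
total_spores,ancestor,12,1.000,0.0010
total_spores,control,10,0.930,0.0021
total_spores,MA,90,0.869,0.0080
spore_germination,ancestor,17,1.000,0.0000
spore_germination,control,10,0.987,0.0003
spore_germination,MA,90,0.519,0.0715
competitive_ability,ancestor,42,0.999,0.0007
competitive_ability,control,10,1.000,0.0004
competitive_ability,MA,90,0.900,0.1247
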