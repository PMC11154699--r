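class,s,r2_gosif_troposif,r2_gppvprm_troposif,r2_gppvprm_gosif
Grassland,2.81,0.22,0.22,0.52
Cropland,4.62,0.45,0.48,0.53
Savanna,4.35,0.56,0.22,0.29
Shrubland,4.35,0.62,0.77,0.84
DeciduousForest,4.17,0.56,0.46,0.55
EvergreenForest,4.02,0.52,0.59,0.59
MixedForest,3.94,0.55,0.44,0.52
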