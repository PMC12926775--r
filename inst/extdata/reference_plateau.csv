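participant,interval,plateau_k,plateau_deviation
lvPPA-1,BL-M3,14,16.96
lvPPA-1,BL-M6,13,12.93
lvPPA-2,BL-M3,13,20.83
lvPPA-2,BL-M6,12,15.95
PCA,BL-M3,13,16.86
PCA,BL-M6,11,11.37
svPPA,BL-M3,11,28.24
svPPA,BL-M6,12,15.19
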