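participant,interval,delta_mm,lower,upper
lvPPA-1,BL-M3,0.021,0.01,0.032
lvPPA-1,BL-M6,0.045,0.034,0.056
lvPPA-1,M3-M6,0.024,0.013,0.035
lvPPA-2,M3-M6,0.024,0.007,0.042
PCA,BL-M3,0.041,0.022,0.06
PCA,BL-M6,0.027,0.007,0.046
svPPA,BL-M3,0.02,0.009,0.031
svPPA,BL-M6,0.031,0.02,0.043
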