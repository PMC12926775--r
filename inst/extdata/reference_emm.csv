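participant,roi,timepoint,emm,lower,upper
lvPPA-1,core,BL,1.81,1.72,1.90
lvPPA-1,core,M3,1.78,1.69,1.87
lvPPA-1,core,M6,1.76,1.67,1.85
lvPPA-1,control,BL,2.15,2.05,2.25
lvPPA-1,control,M3,2.15,2.04,2.25
lvPPA-1,control,M6,2.15,2.05,2.25
lvPPA-2,core,BL,1.93,1.92,1.94
lvPPA-2,core,M3,1.90,1.89,1.91
lvPPA-2,core,M6,1.89,1.88,1.90
lvPPA-2,control,BL,2.15,2.13,2.16
lvPPA-2,control,M3,2.11,2.10,2.13
lvPPA-2,control,M6,2.13,2.11,2.14
PCA,core,BL,1.89,1.88,1.90
PCA,core,M3,1.85,1.85,1.86
PCA,core,M6,1.83,1.83,1.84
PCA,control,BL,2.26,2.24,2.27
PCA,control,M3,2.26,2.25,2.28
PCA,control,M6,2.23,2.21,2.24
svPPA,core,BL,1.78,1.77,1.78
svPPA,core,M3,1.76,1.75,1.76
svPPA,core,M6,1.73,1.73,1.74
svPPA,control,BL,2.35,2.34,2.36
svPPA,control,M3,2.35,2.34,2.36
svPPA,control,M6,2.34,2.33,2.35
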