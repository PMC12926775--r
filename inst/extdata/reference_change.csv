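participant,roi,interval,decline_mm,lower,upper,percent_change
lvPPA-1,core,BL-M3,0.029,0.020,0.038,-1.6
lvPPA-1,core,BL-M6,0.050,0.041,0.058,-2.8
lvPPA-1,core,M3-M6,0.021,0.013,0.029,-1.2
lvPPA-1,control,BL-M3,0.008,-0.006,0.022,-0.4
lvPPA-1,control,BL-M6,0.005,-0.009,0.019,-0.2
lvPPA-1,control,M3-M6,-0.003,-0.017,0.011,0.1
lvPPA-2,core,BL-M3,0.029,0.016,0.041,-1.5
lvPPA-2,core,BL-M6,0.039,0.028,0.05,-2.0
lvPPA-2,core,M3-M6,0.01,-0.001,0.021,-0.5
lvPPA-2,control,BL-M3,0.033,0.012,0.055,-1.5
lvPPA-2,control,BL-M6,0.019,-0.002,0.04,-0.9
lvPPA-2,control,M3-M6,-0.014,-0.035,0.007,0.7
PCA,core,BL-M3,0.032,0.021,0.043,-1.7
PCA,core,BL-M6,0.054,0.043,0.065,-2.9
PCA,core,M3-M6,0.022,0.013,0.032,-1.2
PCA,control,BL-M3,-0.009,-0.031,0.013,0.4
PCA,control,BL-M6,0.028,0.005,0.051,-1.2
PCA,control,M3-M6,0.037,0.018,0.056,-1.6
svPPA,core,BL-M3,0.020,0.011,0.029,-1.1
svPPA,core,BL-M6,0.041,0.032,0.05,-2.3
svPPA,core,M3-M6,0.021,0.012,0.03,-1.2
svPPA,control,BL-M3,0.0001,-0.014,0.014,-0.1
svPPA,control,BL-M6,0.01,-0.005,0.024,-0.4
svPPA,control,M3-M6,0.01,-0.005,0.024,-0.4
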