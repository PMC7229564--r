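subject,x_mean_mm,x_sd_mm,x_rsd,y_mean_mm,y_sd_mm,y_rsd
1,19.55,1.41,0.072,33.14,0.25,0.008
2,14.44,0.41,0.028,31.93,0.19,0.006
3,15.81,1.09,0.069,32.62,0.50,0.015
4,19.53,1.65,0.084,36.90,0.46,0.012
5,26.03,1.56,0.060,30.52,1.47,0.048
6,16.91,1.35,0.080,26.54,0.63,0.024
7,20.31,1.27,0.063,35.46,1.07,0.030
8,24.58,1.45,0.059,32.42,0.45,0.014
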