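biomarker,mu,M,sigma
PA,14.77,14.71,1.40
PD,11.96,11.35,1.12
PT,13.38,12.78,1.55
LPD,233.69,211.36,25.25
MA,17.28,15.19,1.79
SoV,15.30,15.49,2.12
k,7.42,7.49,0.44
h,92.12,82.80,15.21
w,70.72,60.70,10.76
h/w,1.33,1.18,0.29
tor,0.70,0.71,0.02
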