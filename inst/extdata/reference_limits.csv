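index,contrast,median,q1,q3,low_tail_class,high_tail_class
HR,CR6,2.3,0.2,5.9,reduced,increased
HR,CR15,8.1,4.3,13.4,reduced,increased
QTc,CR6,0.004,-0.002,0.010,reduced,increased
QTc,CR15,0.013,0.005,0.019,reduced,increased
ST,CR6,0.008,-0.014,0.030,reduced,increased
ST,CR15,0.005,-0.027,0.032,reduced,increased
TP,CR6,13918.5,7681.4,19471.6,reduced,increased
TP,CR15,-1003.2,-3419.4,327.4,reduced,increased
VLF,CR6,146.7,-230.7,585.6,reduced,increased
VLF,CR15,51.1,-330.3,456.0,reduced,increased
LF,CR6,13683.4,8402.0,18107.7,reduced,increased
LF,CR15,-656.5,-1762.6,-108.0,reduced,increased
LFn,CR6,44.3,23.6,60.6,reduced,increased
LFn,CR15,-8.7,-26.8,1.4,reduced,increased
HF,CR6,26.7,-1019.2,1437.2,reduced,increased
HF,CR15,-216.6,-1156.3,428.0,reduced,increased
HFn,CR6,-42.7,-59.5,-22.4,reduced,increased
HFn,CR15,8.6,-2.6,26.0,reduced,increased
LFHF,CR6,5.89,3.60,10.12,reduced,increased
LFHF,CR15,-0.20,-1.19,0.00,reduced,increased
TP_SBP,CR6,29.7,9.0,58.6,reduced,increased
TP_SBP,CR15,9.8,-6.2,31.2,reduced,increased
TP_DBP,CR6,13.0,4.6,23.4,reduced,increased
TP_DBP,CR15,0.9,-5.0,5.9,reduced,increased
VLF_SBP,CR6,3.0,-6.5,13.4,reduced,increased
VLF_SBP,CR15,2.8,-5.8,15.1,reduced,increased
VLF_DBP,CR6,1.0,-1.4,3.7,reduced,increased
VLF_DBP,CR15,1.0,-1.8,4.0,reduced,increased
LF_SBP,CR6,28.4,13.6,49.0,reduced,increased
LF_SBP,CR15,-0.3,-4.4,4.0,reduced,increased
LF_DBP,CR6,9.7,4.6,16.8,reduced,increased
LF_DBP,CR15,-0.6,-2.9,0.6,reduced,increased
LF_SBPn,CR6,34.1,13.8,50.4,reduced,increased
LF_SBPn,CR15,-18.3,-34.1,-2.2,reduced,increased
LF_DBPn,CR6,11.1,3.0,23.4,reduced,increased
LF_DBPn,CR15,-13.3,-28.1,-1.5,reduced,increased
HF_SBP,CR6,-0.8,-4.6,1.3,reduced,increased
HF_SBP,CR15,6.2,1.4,16.1,reduced,increased
HF_DBP,CR6,0.7,0.0,1.9,reduced,increased
HF_DBP,CR15,0.4,-0.3,2.0,reduced,increased
HF_SBPn,CR6,-32.2,-49.0,-11.5,reduced,increased
HF_SBPn,CR15,18.5,2.4,32.7,reduced,increased
HF_DBPn,CR6,-8.3,-20.9,-2.4,reduced,increased
HF_DBPn,CR15,11.6,0.8,26.0,reduced,increased
LFHF_SBP,CR6,6.72,2.77,13.65,reduced,increased
LFHF_SBP,CR15,-0.49,-1.50,-0.07,reduced,increased
LFHF_DBP,CR6,3.24,0.86,7.07,reduced,increased
LFHF_DBP,CR15,-1.28,-2.82,-0.09,reduced,increased
TP_R,CR6,256.1,45.3,711.5,reduced,increased
TP_R,CR15,710.4,194.4,1684.6,reduced,increased
VLF_R,CR6,7.0,3.2,15.4,reduced,increased
VLF_R,CR15,2.2,0.0,6.6,reduced,increased
LF_R,CR6,478.7,215.8,972.2,reduced,increased
LF_R,CR15,2.2,-24.5,18.2,reduced,increased
LF_Rn,CR6,75.0,59.1,82.9,reduced,increased
LF_Rn,CR15,-2.5,-14.1,-0.7,reduced,increased
HF_R,CR6,-185.1,-326.3,-74.9,reduced,increased
HF_R,CR15,722.4,219.5,1744.9,reduced,increased
HF_Rn,CR6,-70.5,-79.7,-53.0,reduced,increased
HF_Rn,CR15,7.4,2.1,20.0,reduced,increased
LFHF_R,CR6,6.11,3.48,8.29,reduced,increased
LFHF_R,CR15,-0.03,-0.18,-0.01,reduced,increased
Ti,CR6,2.5,1.7,2.9,reduced,increased
Ti,CR15,0.0,-0.4,0.3,reduced,increased
Te,CR6,2.9,2.3,3.6,reduced,increased
Te,CR15,-0.3,-0.9,0.1,reduced,increased
VT,CR6,1.10,0.70,1.69,reduced,increased
VT,CR15,0.32,0.12,0.68,reduced,increased
VT_TI,CR6,0.09,0.02,0.17,reduced,increased
VT_TI,CR15,0.20,0.10,0.36,reduced,increased
VT_TE,CR6,0.08,-0.01,0.22,reduced,increased
VT_TE,CR15,0.21,0.08,0.37,reduced,increased
Ti_frac,CR6,0.03,-0.02,0.07,reduced,increased
Ti_frac,CR15,0.03,-0.01,0.07,reduced,increased
RR,CR6,-7.7,-10.3,-5.5,reduced,increased
RR,CR15,1.1,-1.5,3.4,reduced,increased
V,CR6,3.0,0.9,6.2,reduced,increased
V,CR15,6.1,3.0,10.4,reduced,increased
VO2,CR6,0.14,0.04,0.28,reduced,increased
VO2,CR15,0.28,0.14,0.48,reduced,increased
EDV,CR6,0.0,-3.8,3.5,reduced,increased
EDV,CR15,-1.8,-6.4,1.8,reduced,increased
ESV,CR6,0.4,-1.2,2.4,reduced,increased
ESV,CR15,0.4,-1.7,2.3,reduced,increased
SV,CR6,-0.6,-2.8,1.7,reduced,increased
SV,CR15,-2.2,-5.3,0.1,reduced,increased
CO,CR6,0.2,0.0,0.4,reduced,increased
CO,CR15,0.4,0.1,0.7,reduced,increased
CI,CR6,0.103,0.000,0.203,reduced,increased
CI,CR15,0.206,0.059,0.353,reduced,increased
GPVR,CR6,-78.6,-170.4,6.5,reduced,increased
GPVR,CR15,-131.0,-262.3,-32.2,reduced,increased
SI_stroke,CR6,-0.22,-1.49,0.89,reduced,increased
SI_stroke,CR15,-1.12,-2.85,0.10,reduced,increased
VSI,CR6,-0.128,-0.255,-0.051,reduced,increased
VSI,CR15,-0.229,-0.358,-0.128,reduced,increased
HI,CR6,6.02,4.98,7.26,reduced,increased
HI,CR15,0.28,-0.82,1.08,reduced,increased
BR_LF,CR6,5.05,0.57,10.15,reduced,increased
BR_LF,CR15,-4.32,-9.11,-1.52,reduced,increased
BR_HF,CR6,3.31,-3.89,9.20,reduced,increased
BR_HF,CR15,-6.91,-11.86,-2.82,reduced,increased
IC_HR,CR6,5.98,3.37,10.92,reduced,increased
IC_HR,CR15,-0.13,-1.11,0.41,reduced,increased
IC_SBP,CR6,8.18,2.69,19.93,reduced,increased
IC_SBP,CR15,-1.52,-6.36,0.10,reduced,increased
IC_DBP,CR6,2.04,-2.23,7.74,reduced,increased
IC_DBP,CR15,-2.44,-6.65,1.03,reduced,increased
IC_R,CR6,6.20,3.58,8.46,reduced,increased
IC_R,CR15,-0.04,-0.22,-0.01,reduced,increased
ABI,CR6,-7.74,-18.16,-1.70,reduced,increased
ABI,CR15,0.74,-6.85,11.94,reduced,increased
SRAI,CR6,-1.16,-2.08,-0.39,reduced,increased
SRAI,CR15,1.06,0.03,2.11,reduced,increased
ARI,CR6,-1.17,-3.45,0.26,reduced,increased
ARI,CR15,0.51,-1.18,2.37,reduced,increased
SI,CR6,-37.67,-105.23,-7.31,reduced,increased
SI,CR15,14.52,-26.51,90.98,reduced,increased
SDANN,CR6,59.53,41.02,79.39,reduced,increased
SDANN,CR15,-10.47,-24.62,2.05,reduced,increased
RMSSD,CR6,13.63,0.26,35.57,reduced,increased
RMSSD,CR15,-0.43,-13.94,19.37,reduced,increased
pNN50,CR6,-0.26,-1.29,7.80,reduced,increased
pNN50,CR15,-0.94,-2.35,-0.13,reduced,increased
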