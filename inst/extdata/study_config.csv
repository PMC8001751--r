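variable,units,family,a,b,c,d,noise_sd
body_weight_kg,kg,Gompertz,18.61,0.62,0.01,,1.22
carcass_kg,kg,Logistic,5.44,2.89,0.039,,0.79
dressing_pct,%,Quadratic,47.61,0.24,-0.00282,,3.39
oblique_length_cm,cm,Gompertz,53.27,-0.43,0.0237,,4.00
height_cm,cm,Logistic,54.57,0.77,0.0146,,3.24
tube_cm,cm,Gompertz,7.62,-1.69,0.0284,,0.62
chest_circumference_cm,cm,Logistic,64.27,0.93,0.0178,,2.78
chest_depth_cm,cm,MMF,8.21,6300,21.45,2.68,3.05
rumen_ph,pH,Cubic,6.12,0.04,-0.0015,0.000013,0.52
rumen_volume_ml,mL,Quadratic,-11.23,5.02,0.08,,148.67
rumen_g,g,Gompertz,1600,1.65,0.01,,17.35
reticulum_g,g,Weibull,30.22,25.36,0.0000028,3.25,4.76
omasum_g,g,Quadratic,3.44,-0.15,0.01,,3.99
abomasum_g,g,Quadratic,32.14,-0.14,0.0063,,9.22
rumen_pct,%,MMF,22.52,1900,61.55,2.26,6.64
reticulum_pct,%,Cubic,11.41,-0.31,0.01,-0.0001,2.57
omasum_pct,%,Weibull,10.06,4.69,0.00000000037,5.21,1.96
abomasum_pct,%,MMF,60.93,11000,17.99,2.70,6.43
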