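cell_line,id,rho,alpha_exp,b0,Td,Tm,derived,reference
HT-1080,1,2.7e-3,0.012,468,24,0.063,b0,5
HT-1080,2,2.9e-3,0.128,371,24,0.075,b0,5
HT-1080,3,1.6e-3,0.078,532,24,0.107,b0,5
HT-1080,4,2.1e-3,0.078,638,24,0.075,b0,5
HT-1080,5,1.5e-3,0.069,548,24,0.129,b0,5
HT-1080,6,1.2e-3,0.069,687,24,0.082,b0,5
HT-1080,7,NA,0.110,288,24,0.110,,58
MDA-MB-231,8,1.0e-3,0.023,800,38,0.338,,31;51
MDA-MB-231,9,1.2e-3,0.042,930,38,0.075,,31;51
MDA-MB-231,10,2.3e-3,0.044,800,38,0.095,,31;51
MDA-MB-231,11,NA,0.040,288,38,0.476,,58
MDA-MB-468,12,1.2e-3,0.031,800,47,0.154,,51
HaCaT,13,1.2e-3,0.043,900,19,0.156,,49;50
HaCaT,14,1.7e-3,0.132,900,19,0.017,,49;50
HaCaT,15,2.5e-2,0.029,NA,19,0.078,rho,21
Saos-2: HTB 85,16,NA,0.010,800,37,5.851,,59;60
Caco-2,17,1.2e-3,0.014,882,80,0.385,rho;b0,61
BEAS,18,NA,0.054,500,26,0.188,,18
MCF-7,19,NA,0.031,500,38,0.741,,
MCF-7,20,NA,0.040,287,38,0.54,,58
NIH/3T3,21,1.3e-4,0.062,933,20,0.002,,new data
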