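formulation,Fa,Fb,Cmax,tmax,AUC_0_inf,AUC_0_t,Cmax_liver
IR,45.385,1.585,2.00,0.96,18.00,14.00,5.00
P5,71.330,2.497,12.00,0.80,22.00,22.00,35.00
C5,99.883,3.496,19.00,0.56,31.00,31.00,55.00
P9,91.637,3.207,6.00,0.80,29.00,28.00,18.00
C9,80.126,2.804,15.00,0.50,25.00,25.00,42.00
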