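dose_mg,route,parameter,predicted,observed
75,po,Cmax,1.60,1.81
75,po,tmax,0.94,0.50
75,po,AUC_0_inf,9.43,10.87
75,po,AUC_0_t,5.76,6.50
300,po,Cmax,5.03,5.47
300,po,tmax,0.92,0.50
300,po,AUC_0_inf,21.32,17.70
300,po,AUC_0_t,17.69,15.95
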