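dose_mg,route,parameter,predicted,observed
1,iv_bolus,AUC_0_inf,11.45,10.80
1,iv_bolus,AUC_0_t,11.31,10.71
10,iv_bolus,AUC_0_inf,114.45,121.41
10,iv_bolus,AUC_0_t,113.08,121.25
100,iv_infusion,AUC_0_inf,1144.50,1137.60
100,iv_infusion,AUC_0_t,1142.40,1135.40
300,iv_infusion,AUC_0_inf,3433.50,2406.50
300,iv_infusion,AUC_0_t,3427.20,2393.30
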