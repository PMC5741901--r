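phase,mirna,fc_prog_median,fc_prog_q1,fc_prog_q3,fc_nonprog_median,fc_nonprog_q1,fc_nonprog_q3,bl_nonprog_median,bl_nonprog_q1,bl_nonprog_q3,bl_prog_median,bl_prog_q1,bl_prog_q3,fd_baseline,auc,ci_low,ci_high,sens_pct,spec_pct
pilot,miR-22,4.3,2.8,12.1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
pilot,miR-382,4.1,1.7,6.9,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
pilot,miR-486-3p,4.1,0.9,8.6,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
validation,miR-22,2.5,-2.2,15.3,3.4,2.3,12.6,7.4,4.1,8.2,3.1,1.8,7.3,19.7,0.68,0.48,0.82,63,100
validation,miR-382,1.2,-2.1,2.7,2.4,1.0,2.6,1.1,0.0,1.8,-0.2,-0.5,1.9,2.5,0.57,0.40,0.75,75,58
validation,miR-486-3p,2.2,-2.5,6.0,1.0,-1.4,3.0,3.4,1.7,3.9,3.9,2.6,5.0,-1.4,0.55,0.36,0.72,50,75
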