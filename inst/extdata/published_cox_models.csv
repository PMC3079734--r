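model,covariate,hr,p,printed_overall_hr
calbindin,log_calbindin,1.750,0.0063,4.704
calbindin,log_recip_abeta42,2.454,0.0001,4.704
calbindin,age_at_lp,1.096,0.0002,4.704
tau,log_tau,1.467,0.0262,3.619
tau,log_recip_abeta42,2.247,0.0001,3.619
tau,age_at_lp,1.098,0.0003,3.619
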