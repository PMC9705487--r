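treatment,pool,compartment,mean_pct,se_pct,bracketed
urea,donor_shoots,T_ra_C,37,2.5,FALSE
urea,donor_roots,T_ra_C,1.8,0.4,FALSE
urea,soil,T_ra_C,0.69,0.11,FALSE
urea,receiver_roots,T_ra_C,0.34,0.09,FALSE
urea,receiver_shoots,T_ra_C,0.14,0.01,FALSE
urea,total,T_ra_C,40,3.1,FALSE
urea,unknown,T_ra_C,60,3.1,FALSE
decomposition,donor_shoots,T_ra_C,40,0.2,TRUE
decomposition,donor_roots,T_ra_C,0.33,0.07,TRUE
decomposition,soil,T_ra_C,6.8,0.8,FALSE
decomposition,receiver_roots,T_ra_C,1.9,0.5,FALSE
decomposition,receiver_shoots,T_ra_C,4.0,0.6,FALSE
decomposition,total,T_ra_C,53,2.1,FALSE
decomposition,unknown,T_ra_C,47,2.1,FALSE
exudation,donor_shoots,T_ra_C,29,5.0,TRUE
exudation,donor_roots,T_ra_C,1.2,0.3,TRUE
exudation,soil,T_ra_C,0.40,0.09,FALSE
exudation,receiver_roots,T_ra_C,0.05,0.01,FALSE
exudation,receiver_shoots,T_ra_C,0.09,0.02,FALSE
exudation,total,T_ra_C,30,5.5,FALSE
exudation,unknown,T_ra_C,70,5.5,FALSE
defoliation,donor_shoots,T_ra_C,23,6.2,TRUE
defoliation,donor_roots,T_ra_C,0.57,0.15,FALSE
defoliation,soil,T_ra_C,0.67,0.10,FALSE
defoliation,receiver_roots,T_ra_C,0.16,0.04,FALSE
defoliation,receiver_shoots,T_ra_C,0.08,0.02,FALSE
defoliation,total,T_ra_C,24,6.5,FALSE
defoliation,unknown,T_ra_C,76,6.5,FALSE
sterile,donor_shoots,T_ra_C,24,8.4,FALSE
sterile,donor_roots,T_ra_C,0.47,0.26,FALSE
sterile,soil,T_ra_C,0.53,0.09,FALSE
sterile,receiver_roots,T_ra_C,0.36,0.08,FALSE
sterile,receiver_shoots,T_ra_C,0.38,0.06,FALSE
sterile,total,T_ra_C,25,7.9,FALSE
sterile,unknown,T_ra_C,75,7.9,FALSE
fungi,donor_shoots,T_ra_C,22,6.7,FALSE
fungi,donor_roots,T_ra_C,0.84,0.13,FALSE
fungi,soil,T_ra_C,0.39,0.07,FALSE
fungi,receiver_roots,T_ra_C,0.09,0.02,FALSE
fungi,receiver_shoots,T_ra_C,0.17,0.05,FALSE
fungi,total,T_ra_C,24,7.0,FALSE
fungi,unknown,T_ra_C,76,7.0,FALSE
weevil,donor_shoots,T_ra_C,25,6.5,FALSE
weevil,donor_roots,T_ra_C,2.9,0.7,FALSE
weevil,soil,T_ra_C,0.51,0.14,FALSE
weevil,receiver_roots,T_ra_C,0.28,0.07,FALSE
weevil,receiver_shoots,T_ra_C,0.07,0.01,FALSE
weevil,total,T_ra_C,29,7.4,FALSE
weevil,unknown,T_ra_C,71,7.4,FALSE
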