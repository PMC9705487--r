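treatment,mean_pct,se_pct
urea,3.2,1.1
decomposition,9.3,1.7
exudation,1.1,0.3
defoliation,2.4,0.3
sterile,6.0,0.8
fungi,2.5,0.5
weevil,2.5,0.3
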