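direction,pool,compartment,mean_pct,se_pct
clover_to_grass,donor_roots,L_ab_C,18,1.9
clover_to_grass,donor_shoots,T_ra_C,23,2.0
clover_to_grass,donor_roots,T_ra_C,0.72,0.11
clover_to_grass,soil,T_ra_C,0.31,0.07
clover_to_grass,receiver_roots,T_ra_C,0.004,0.001
clover_to_grass,receiver_shoots,T_ra_C,0.004,0.001
clover_to_grass,receiver_roots,R_ec_C,0.002,0.0006
clover_to_grass,soil,R_ec_C,n.d.,n.d.
clover_to_grass,total,,42.0,4.1
grass_to_clover,donor_roots,L_ab_C,4.0,0.8
grass_to_clover,donor_shoots,T_ra_C,67,10
grass_to_clover,donor_roots,T_ra_C,1.6,0.3
grass_to_clover,soil,T_ra_C,0.52,0.16
grass_to_clover,receiver_roots,T_ra_C,0.52,0.09
grass_to_clover,receiver_shoots,T_ra_C,0.02,0.003
grass_to_clover,receiver_roots,R_ec_C,0.005,0.002
grass_to_clover,soil,R_ec_C,0.21,0.004
grass_to_clover,total,,73.7,11.3
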