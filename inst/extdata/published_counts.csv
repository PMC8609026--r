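population,cohort,case_n,control_n,excluded_n
pediatric,broad,1139035,11036263,0
pediatric,mca_id_dd_e,94714,12080584,0
pediatric,conservative,28348,12146950,0
critically_ill_newborn,broad,29348,1148695,125719
critically_ill_newborn,mca_id_dd_e,8723,1295039,0
critically_ill_newborn,conservative,1924,1301838,0
critically_ill_newborn,broad_nicu_share,29348,36347,0
critically_ill_newborn,mca_id_dd_e_nicu_share,8723,56972,0
critically_ill_newborn,conservative_nicu_share,1924,63771,0
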