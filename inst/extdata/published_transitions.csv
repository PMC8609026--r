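population,cohort,sample_size,possible_to_probable,possible_to_definite,probable_to_definite,genetic_test_to_definite,other_cpt_hcpcs_to_definite,combined_published
critically_ill_newborn,broad,29348,9.2,4.6,0.7,0.0,0.0,5.3
critically_ill_newborn,mca_id_dd_e,8723,17.7,6.1,0.4,0.0,0.0,6.5
critically_ill_newborn,conservative,1924,25.9,29.0,12.6,3.3,0.0,41.6
pediatric,broad,1139035,3.2,0.9,0.2,0.1,0.2,1.1
pediatric,mca_id_dd_e,94714,7.7,2.0,0.6,0.0,0.0,2.6
pediatric,conservative,28348,16.6,12.4,3.4,3.3,0.0,15.8
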