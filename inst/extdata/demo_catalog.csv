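kind,code,code_system,tier,easy_to_diagnose,clinical_presentation_group,organ_system,anomaly_flag,mca_specific_flag,id_flag,dd_flag,e_flag,age_min_days,age_max_days,category,unit
diagnosis,Q24.9,ICD10,possible,FALSE,congenital_anomalies,cardiovascular,TRUE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,Q04.9,ICD10,possible,FALSE,congenital_anomalies,nervous_system,TRUE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,Q64.9,ICD10,possible,FALSE,congenital_anomalies,genitourinary,TRUE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,Q79.9,ICD10,probable,FALSE,congenital_anomalies,musculoskeletal,TRUE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,Q33.9,ICD10,possible,FALSE,congenital_anomalies,respiratory,TRUE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,Q89.7,ICD10,probable,FALSE,congenital_anomalies,multiple,TRUE,TRUE,FALSE,FALSE,FALSE,,,,
diagnosis,759.7,ICD9,probable,FALSE,congenital_anomalies,multiple,TRUE,TRUE,FALSE,FALSE,FALSE,,,,
diagnosis,746.9,ICD9,possible,FALSE,congenital_anomalies,cardiovascular,TRUE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,742.9,ICD9,possible,FALSE,congenital_anomalies,nervous_system,TRUE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,741.90,ICD9,possible,FALSE,congenital_anomalies,nervous_system,TRUE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,F79,ICD10,probable,FALSE,mental_behavioral_neurodevelopmental,nervous_system,FALSE,FALSE,TRUE,FALSE,FALSE,,,,
diagnosis,318.0,ICD9,probable,FALSE,mental_behavioral_neurodevelopmental,nervous_system,FALSE,FALSE,TRUE,FALSE,FALSE,,,,
diagnosis,F88,ICD10,possible,FALSE,mental_behavioral_neurodevelopmental,nervous_system,FALSE,FALSE,FALSE,TRUE,FALSE,,,,
diagnosis,R62.0,ICD10,possible,FALSE,symptoms_signs,nervous_system,FALSE,FALSE,FALSE,TRUE,FALSE,0,2190,,
diagnosis,G40.909,ICD10,possible,FALSE,nervous_system,nervous_system,FALSE,FALSE,FALSE,FALSE,TRUE,,,,
diagnosis,345.90,ICD9,possible,FALSE,nervous_system,nervous_system,FALSE,FALSE,FALSE,FALSE,TRUE,,,,
diagnosis,R56.9,ICD10,possible,FALSE,nervous_system,nervous_system,FALSE,FALSE,FALSE,FALSE,TRUE,0,6570,,
diagnosis,G71.20,ICD10,probable,FALSE,nervous_system,musculoskeletal,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,G93.9,ICD10,possible,FALSE,nervous_system,nervous_system,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,E88.9,ICD10,probable,FALSE,endocrine_nutritional_metabolic,endocrine,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,E03.1,ICD10,probable,FALSE,endocrine_nutritional_metabolic,endocrine,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,E70.9,ICD10,definite,FALSE,endocrine_nutritional_metabolic,endocrine,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,E75.23,ICD10,definite,FALSE,endocrine_nutritional_metabolic,nervous_system,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,270.1,ICD9,definite,FALSE,endocrine_nutritional_metabolic,endocrine,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,Q90.9,ICD10,definite,FALSE,congenital_anomalies,multiple,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,E84.0,ICD10,definite,TRUE,respiratory,respiratory,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,277.00,ICD9,definite,TRUE,respiratory,respiratory,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,D57.1,ICD10,definite,TRUE,blood_disorders,blood,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,M41.9,ICD10,possible,FALSE,musculoskeletal,musculoskeletal,FALSE,FALSE,FALSE,FALSE,FALSE,0,28,,
diagnosis,P94.2,ICD10,probable,FALSE,perinatal_period,nervous_system,FALSE,FALSE,FALSE,FALSE,FALSE,0,365,,
diagnosis,H90.3,ICD10,possible,FALSE,sense_organs,sense_organs,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
diagnosis,D61.09,ICD10,probable,FALSE,blood_disorders,blood,FALSE,FALSE,FALSE,FALSE,FALSE,,,,
procedure,81415,CPT,,,,,,,,,,,,genetic_test,
procedure,81220,CPT,,,,,,,,,,,,genetic_test,
procedure,81228,CPT,,,,,,,,,,,,genetic_test,
procedure,81479,CPT,,,,,,,,,,,,genetic_test,
procedure,S3870,HCPCS,,,,,,,,,,,,genetic_test,
procedure,95816,CPT,,,,,,,,,,,,other_workup,
procedure,70551,CPT,,,,,,,,,,,,other_workup,
procedure,93306,CPT,,,,,,,,,,,,other_workup,
procedure,20200,CPT,,,,,,,,,,,,other_workup,
revenue,0173,,,,,,,,,,,,,,NICU
revenue,0174,,,,,,,,,,,,,,NICU
revenue,0202,,,,,,,,,,,,,,PICU
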