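case_id,patient_id,sex,current_age,race,age_at_diagnosis,age_at_diagnosis_is_upper_bound,bmi_min,bmi_max,hba1c_min,hba1c_max,regimen,uses_insulin_long_term,family_history_diabetes,family_members,multigenerational_family_history,ketosis_history_adult,antibody_status,c_peptide_status,pattern
1,AD-01,M,41,Black,35,FALSE,23.9,27.8,5.3,11.2,Metformin,FALSE,TRUE,Father; brother; uncle,TRUE,TRUE,negative_documented,normal_or_high,KPD
2,AD-02,F,67,White,42,FALSE,21.0,25.2,6.2,9.1,Metformin; basal insulin; liraglutide,TRUE,FALSE,,FALSE,FALSE,negative_documented,untested,ISNM
3,AD-03,M,61,White,35,FALSE,16.8,23.8,7.5,8.6,Metformin; glipizide,FALSE,TRUE,Mother; sister,TRUE,FALSE,negative_documented,untested,ISNM
4,AD-04,F,62,White,52,FALSE,23.0,24.0,6.2,6.7,Metformin; glimepiride,FALSE,FALSE,,FALSE,FALSE,negative_documented,untested,ISNM
5,AD-05,M,69,White,58,FALSE,23.4,27.3,7.0,7.3,Metformin,FALSE,FALSE,,FALSE,FALSE,negative_documented,untested,ISNM
6,AD-06,M,74,White,68,FALSE,22.1,24.0,6.1,6.4,Diet,FALSE,TRUE,Father,FALSE,FALSE,negative_documented,untested,MARD
7,AD-07,F,72,Asian,60,FALSE,18.5,22.5,5.8,8.8,Metformin; empagliflozin,FALSE,FALSE,,FALSE,FALSE,negative_documented,untested,ISNM
8,AD-08,M,84,Asian,67,FALSE,19.2,22.2,6.2,7.3,Glipizide,FALSE,FALSE,,FALSE,FALSE,negative_documented,untested,MARD
9,AD-09,M,67,White,62,TRUE,25.6,25.6,6.2,6.7,Pioglitazone; metformin; prednisone,FALSE,FALSE,,FALSE,FALSE,negative_documented,untested,MARD
10,AD-10,M,76,White,70,TRUE,24.1,26.2,5.5,6.2,Sitagliptin,FALSE,FALSE,,FALSE,FALSE,negative_documented,untested,MARD
11,AD-11,F,70,White,65,FALSE,22.3,25.7,5.5,6.1,Metformin,FALSE,FALSE,,FALSE,FALSE,negative_documented,untested,MARD
12,AD-12,M,89,White,77,FALSE,17.5,21.8,5.8,6.3,Metformin (discontinued),FALSE,FALSE,,FALSE,FALSE,negative_documented,untested,MARD
13,AD-13,F,77,White,58,FALSE,21.8,25.6,5.6,9.4,Diet,FALSE,FALSE,,FALSE,FALSE,negative_documented,untested,ISNM
14,AD-14,M,68,White,49,FALSE,22.4,25.9,6.6,8.1,Metformin,FALSE,TRUE,Brother,FALSE,FALSE,negative_documented,untested,ISNM
15,AD-15,F,83,Unknown,67,FALSE,18.9,21.5,5.3,6.1,Diet,FALSE,TRUE,Brother,FALSE,FALSE,negative_documented,untested,MARD
16,AD-16,M,54,Unknown,44,FALSE,23.3,26.2,,,Metformin,FALSE,FALSE,,FALSE,FALSE,negative_documented,untested,ISNM
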