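intervention,label,mean,sd,qi_low,qi_high,source
tobacco,Tobacco screening and brief counseling,1.5,0.22,1.1,1.9,simulated
alcohol,Alcohol misuse screening and brief counseling,1.2,0.47,0.51,2.2,simulated
hypertension,Hypertension screening and treatment,2.9,1.0,1.4,5.2,simulated
condoms,Free condoms offered to a patient,0.33,0.12,0.12,0.59,simulated
influenza_50plus,Influenza vaccine (>50 years),2.1,0.45,1.4,3.1,simulated
influenza_15_49,Influenza vaccine (15-49 years),0.067,0.022,0.030,0.12,simulated
obesity,Obesity screening (adults) and brief intervention,6.0,2.0,NA,NA,literature
depression,Depression screening and counseling,0.50,0.16,NA,NA,literature
hiv,HIV-risk screening,0.27,0.09,NA,NA,literature
syphilis,Syphilis-risk screening,0.030,0.010,NA,NA,literature
diabetes,Diabetes screening and treatment (>25 yr),2.0,0.66,NA,NA,literature
cholesterol,Hypercholesterolemia screening and treatment,2.5,0.83,NA,NA,literature
colonoscopy,Colon cancer screening (colonoscopy),33,11,NA,NA,literature
mammography,Breast cancer screening and treatment (mammography),17,5.6,NA,NA,literature
pap_smear,Pap smears (cervical cancer screening),10,3.3,NA,NA,literature
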