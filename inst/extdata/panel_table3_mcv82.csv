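variable,label,sex,lower,upper,bound_style,units
wbc,White blood cells,male,4.0,9.2,interval,10^9/L
wbc,White blood cells,female,3.7,9.2,interval,10^9/L
neut_pct,Neutrophil,any,50,70,interval,%
plt,Platelets,any,100,300,interval,10^9/L
rbc,Red blood cells,male,4.1,5.7,interval,10^12/L
rbc,Red blood cells,female,3.7,5.1,interval,10^12/L
hgb,Hemoglobin,male,131,172,interval,g/L
hgb,Hemoglobin,female,113,151,interval,g/L
hct,Hematocrit,male,0.38,0.51,interval,fraction
hct,Hematocrit,female,0.34,0.45,interval,fraction
mcv,Mean corpuscular volume,male,83.9,99.1,interval,fL
mcv,Mean corpuscular volume,female,82.6,99.1,interval,fL
mch,Mean corpuscular hemoglobin,male,27.8,33.8,interval,pg
mch,Mean corpuscular hemoglobin,female,26.9,33.3,interval,pg
mchc,Mean corpuscular hemoglobin concentration,male,320,355,interval,g/L
mchc,Mean corpuscular hemoglobin concentration,female,322,362,interval,g/L
glucose,Blood sugar,any,3.9,6.1,interval,mmol/L
tc,Total cholesterol,any,,5.18,upper_only,mmol/L
tg,Triglycerides,any,,1.70,upper_only,mmol/L
ldl_c,LDL cholesterol,any,,3.37,upper_only,mmol/L
hdl_c,HDL cholesterol,any,1.04,,lower_only,mmol/L
tbil,Total bilirubin,any,3.4,17.1,interval,umol/L
dbil,Direct bilirubin,any,,3.4,upper_only,umol/L
alt,Alanine transaminase,any,,55,upper_only,U/L
alb,Albumin,any,35,55,interval,g/L
glob,Globulin,any,9,34,interval,g/L
bun,Blood urea nitrogen,any,2.9,8.2,interval,mmol/L
crea,Creatinine,any,53,140,interval,umol/L
sua,Serum uric acid,any,240,490,interval,umol/L
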