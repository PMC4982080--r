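study_id,country,age_range,mean_age,pct_male,n_baseline,trauma_type,timepoints,informant,instruments,measure_type,acute_timing
bryant,United Kingdom,5-16,12.3,55,81,accidental_injury,2 weeks; 3 months; 6 months,child,CIES; CPTSD-RI,0,0
coville,United Kingdom,7-17,11.2,68,66,picu_admission,3 months; 1 year,child,CRIES,0,
digallo,United Kingdom,5-18,10.2,67,50,mva,<4 weeks; 3 months,child,CRIES; CPTSD-RI,0,0
doronlamarca,United States,6-18,13.3,75,157,accidental_injury,<4 weeks; 3 months; 1 year,child,CPTSD-RI,0,0
hajek,United States,8-15,11.9,63,285,tbi_orthopaedic,<4 weeks; 3 months; 1 year,parent,PCL-C/PR,0,0
hitchcock,Australia,7-17,11.9,80,50,accidental_injury,1 month; 3 months,child,CPSS,0,1
lagreca,United States,8-12,,42,442,hurricane,3 months; 7 months,child,CPTSD-RI,0,
landolt_a,Switzerland,6.5-14.5,9.8,54,68,mva,4-6 weeks; 1 year,child,CPTSD-RI,0,1
landolt_b,Switzerland,6.5-16,10.4,61,138,accidental_injury,5-6 weeks; 1 year,child,CPTSD-RI,0,1
lebrocque,Australia,6-16,10.7,63,169,accidental_injury,4-6 weeks; 6 months,child,CIES,0,1
meiserstedman_a,United Kingdom,10-16,13.8,64,93,assault_mva,<4 weeks; 6 months,child,ADIS-PTSD,1,0
meiserstedman_b,United Kingdom,7-10,9.3,54,52,mva,<4 weeks; 6 months,child,CAPS-CA,1,0
meiserstedman_unpub,United Kingdom,8-17,14.1,58,226,accidental_injury,<4 weeks; 2 months,child,CPTSDI,1,0
mirza,United Kingdom,8-16,13.6,64,119,mva,4-6 weeks; 6 months,child,FRI,0,1
nixon,Australia,7-17,12.2,61,90,accidental_injury,3 months; 6 months,child,CAPS-CA; CPSS,1,
nugent,United States,8-18,13.2,61,82,accidental_injury_assault,6 weeks; 6 months,child,CAPS-CA,1,1
oconnor,United States,14-17,,71,120,tbi,3 months; 1 year,child,UCLA-PTSD-RI,0,
ostrowski,United States,8-18,13.4,56,45,accidental_injury,6 weeks; 7 months,child,CAPS-CA,1,1
pervanidou,Greece,7-18,11.0,71,56,mva,1 month; 6 months,child,K-SADS-PTSD; CPTSD-RI,1,1
saxe,United States,6-16,11.7,54,24,burns,<4 weeks; 6 months,child,CPTSD-RI,0,0
schafer,Germany,8-18,13.6,58,72,mva,<1 week; 3 months,child,CIES,0,0
selfbrown,United States,8-16,11.6,49,426,hurricane,3 months; 13 months,child,UCLA-PTSD-RI,0,
sturms,Netherlands,8-15,12.2,53,49,accidental_injury,3 months; 6 months,child,CIES,0,
zatzick,United States,12-18,15.9,68,108,accidental_injury_assault,<4 weeks; 2 months; 5 months; 1 year,child,UCLA-PTSD-RI,0,0
zehnder_a,Switzerland,7-16,11.3,58,50,mva,<4 weeks; 2 months; 6 months,child,CAPS-CA,1,0
zehnder_b,Switzerland,6-15,9.8,58,101,accidental_injury,5-6 weeks; 1 year,child,CPTSD-RI,0,1
zhang,China,,16.9,43,548,earthquake,6 months; 1 year,child,PCL-C,0,
zink,United States,7-15,10.8,60,143,mva,2 months; 6 months,child,DICA-R-PTSD,1,
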