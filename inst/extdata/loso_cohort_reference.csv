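subject,maternal_status,status_detail,ga_weeks,fetal_weight_g,maternal_age_years,bmi_kg_m2,accuracy_pct
1,Normal,,20.6,393,33,32.4,93.8
2,Exists,autoimmune disease and protein S hypothyroidism,39.3,2835,35,21.0,90.2
3,Normal,,20.1,355,31,23.9,88.5
4,Exists,uterine/appendix disease and autoimmune disease,26.2,937,32,15.8,88.7
5,Exists,uterine/appendix disease and autoimmune disease,33.4,1854,28,33.0,68.5
6,Exists,history of hepatitis B,30.0,1310,22,24.1,92.9
7,Exists,others (history of hydatidiform mole),26.3,1023,24,25.9,92.9
8,Normal,,24.0,757,31,24.2,93.8
9,Exists,uterine/appendix disease,29.2,1239,35,21.0,89.4
10,Exists,autoimmune disease and first birth in old age,38.3,2267,35,21.3,94.4
11,None,,35.1,,36,,97.0
12,Exists,respiratory disease and uterine and appendage disease,39.2,2892,45,35.6,86.9
13,None,,39.3,3138,30,26.2,94.1
14,Normal,,35.4,2462,41,21.7,90.5
15,Normal,,25.3,916,38,20.0,84.3
16,None,,35.1,2281,32,21.9,97.1
17,Exists,autoimmune disease,26.0,919,32,26.9,86.4
18,Exists,uterine/appendix disease and autoimmune disease,29.0,1314,34,21.5,94.1
19,Exists,uterine/appendix disease,24.3,809,29,24.7,77.7
20,Normal,,27.2,1019,22,23.1,86.8
21,Normal,,29.2,1150,22,23.8,84.2
22,Exists,blood disease,29.4,1445,41,20.4,86.5
23,Exists,uterine/appendix disease and autoimmune disease,34.0,2252,34,22.5,85.0
24,Exists,uterine/appendix disease,28.5,1383,29,25.6,90.4
25,Exists,autoimmune disease,30.6,1481,33,20.9,95.0
26,Exists,autoimmune disease,31.6,,25,20.1,81.0
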