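patient_id,stage,risk_group,status,marrow_involved,ploidy,volume_ml,n_single_ctcs,n_clusters
1,Diagnosis,Low,TD,FALSE,Diploid,8.2,24,1
2,Diagnosis,Low,ADF,FALSE,-,3.0,0,0
3,Diagnosis,High,DOD,TRUE,Hyperdiploid,4.0,654,47
4,Diagnosis,High,ADF,TRUE,Hyperdiploid,6.0,0,18
5,Diagnosis,High,ADF,TRUE,Diploid,7.8,88,307
6,Diagnosis,High,ADF,FALSE,Hyperdiploid,8.0,48,708
7,Diagnosis,High,ADF,FALSE,Diploid,7.4,72,1
8,Diagnosis,High,ADF,TRUE,Diploid,1.6,0,0
9,Diagnosis,High,DOD,TRUE,Diploid,5.0,29,11
10,Diagnosis,High,ADF,TRUE,Diploid,5.0,389,149
11,Diagnosis,High,ADF,TRUE,Diploid,4.1,28,3
12,Diagnosis,High,DOD,TRUE,Hyperdiploid,4.0,522,19
13,Diagnosis,High,DOD,TRUE,Diploid,2.2,29,2
14,Diagnosis,High,DOD,TRUE,Diploid,8.0,46,725
15,Diagnosis,High,ADF,TRUE,Diploid,10.0,145,18
16,Diagnosis,High,ADF,TRUE,Diploid,3.4,60,1
17,Diagnosis,High,ADF,TRUE,Diploid,4.5,78,3
18,Diagnosis,High,DOD,TRUE,-,7.0,0,0
19,Relapse,Low,ADF,FALSE,-,1.5,0,1
20,Relapse,Low,DOD,FALSE,-,6.0,0,0
21,Relapse,Intermediate,ADF,FALSE,-,8.5,0,0
22,Relapse,High,DOD,FALSE,Hyperdiploid,6.0,0,2
23,Relapse,High,DOD,FALSE,Hyperdiploid,7.8,304,71
24,Relapse,High,DOD,TRUE,Diploid,3.0,92,7
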