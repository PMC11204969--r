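"study_id","hr","ci_low","ci_high","p_value"
"synthetic_study_01",0.531,0.312,0.904,0.011
"synthetic_study_02",0.681,0.424,1.094,0.12
"synthetic_study_03",0.931,0.564,1.536,0.77
"synthetic_study_04",1.081,0.65,1.799,0.76
"synthetic_study_05",1.251,0.757,2.067,0.37
"synthetic_study_06",1.381,0.849,2.248,0.2
"synthetic_study_07",1.511,0.884,2.584,0.099
"synthetic_study_08",1.581,0.971,2.573,0.067
"synthetic_study_09",1.631,0.938,2.836,0.05
"synthetic_study_10",1.811,1.112,2.95,0.018
"synthetic_study_11",1.941,1.143,3.297,0.008
"synthetic_study_12",2.081,1.186,3.651,0.0034
"synthetic_study_13",2.128,1.356,3.34,0.0025
"synthetic_study_14",2.251,1.391,3.644,0.0012
"synthetic_study_15",2.431,1.495,3.953,0.00038
"synthetic_study_16",2.931,1.762,4.877,1.7e-05
"synthetic_study_17",3.181,1.965,5.149,3.7e-06
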