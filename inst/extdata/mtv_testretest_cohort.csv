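patient_id,psa_ng_ml,gleason,r1_scan1,r2_scan1,r1_scan2,r2_scan2
P01,0.15,7 (4 + 5),0,0,0,0
P02,4.35,6 (3 + 3),4.81,5.88,4.81,5.88
P03,104.5,9 (4 + 5),395.7,404.02,399.18,402.22
P04,0.14,9 (4 + 5),59.91,62.59,82.42,66.9
P05,0.66,9 (5 + 4),6.42,6.77,5.18,7.56
P06,0.22,9 (5 + 4),3.78,4.67,3.78,4.67
P07,56.3,presumptive,38.89,35.59,41.36,22.49
P08,95.5,7 (4 + 3),206.38,247.85,236.35,221.08
P09,276.3,9 (4 + 5),643.19,741.4,643.19,642.43
P10,0.04,presumptive,0,0,0,0
P11,0.64,9 (4 + 5),7.78,8.33,7.78,8.33
P12,2.8,lymph node biopsy,31.49,44.68,30.53,46.24
P13,40.1,10 (5 + 5),464.53,587.13,552.7,515.05
P14,19.7,7 (3 + 4),18.87,22.83,18.87,22.83
P15,2.5,bone biopsy,2.26,1.96,2.26,1.96
P16,54.1,9 (5 + 4),85.89,102.6,92.3,86.56
P17,2.5,9 (5 + 4),21.78,21.81,22.29,21.81
P18,2.5,9 (5 + 4),6.52,6.31,5.53,7.34
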