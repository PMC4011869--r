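group,subgroup,parameter,initial_cm,initial_sd,final_cm,final_sd,normalized_total_change,ntc_sd
AP,Mandible,AMF-GO,6.46,0.49,14.51,0.38,1.26,0.17
AP,Mandible,GO-PMF,4.27,0.29,9.30,0.23,1.19,0.18
AP,Anterior (Body),NO-PMF,2.60,0.17,5.61,0.20,1.16,0.14
AP,Anterior (Body),MMF-PMF,1.15,0.10,2.61,0.35,1.27,0.26
AP,Anterior (Body),AMF-MMF,1.15,0.15,2.72,0.22,1.41,0.39
AP,Anterior (Body),AMF-NO,4.77,0.35,10.61,0.46,1.23,0.09
AP,Posterior (Ramus),CP-MP,1.20,0.12,2.87,0.16,1.43,0.33
AP,Posterior (Ramus),GO-NO,1.75,0.18,4.24,0.40,1.46,0.43
AP,Posterior (Ramus),CP-LP,1.33,0.07,3.26,0.20,1.47,0.25
SI,,GO-CP,3.53,0.13,8.14,0.40,1.31,0.12
SI,,GO-LP,3.25,0.04,7.58,0.26,1.33,0.07
SI,,GO-MP,2.99,0.05,7.40,0.21,1.47,0.08
AI,,GT-CP,6.06,0.29,12.19,0.52,1.01,0.07
AI,,GT-LP,6.96,0.24,14.69,0.18,1.11,0.06
AI,,AMF-CP,6.74,0.39,14.52,0.71,1.16,0.10
AI,,GT-MP,6.17,0.28,13.61,0.12,1.21,0.09
AI,,AMF-LP,7.69,0.37,17.09,0.39,1.23,0.09
AI,,AMF-MP,7.09,0.41,16.30,0.32,1.30,0.12
ML,,Bi-AMF,1.25,0.11,1.82,0.16,0.45,0.08
ML,,Bi-PMF,3.62,0.10,5.40,0.16,0.49,0.05
ML,,Bi-CP,5.06,0.14,7.81,0.29,0.54,0.05
ML,,Bi-MP,3.97,0.15,6.31,0.28,0.59,0.07
ML,,Bi-MMF,2.46,0.07,3.93,0.11,0.60,0.06
ML,,Bi-LP,6.65,0.18,11.33,0.38,0.71,0.06
ML,,Bi-GO,5.43,0.35,10.66,0.23,0.97,0.12
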