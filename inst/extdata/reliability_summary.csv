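analysis,occasion,session,observer,variable,cv,tem,percent_tem,r
inter,A,1,,height,0.05,0.90,0.53,0.98
inter,A,2,,height,0.05,1.64,0.98,0.96
inter,A,1,,weight,0.23,0.97,1.37,0.99
inter,A,2,,weight,0.23,0.30,0.43,0.99
inter,A,1,,muac,0.17,0.73,2.53,0.98
inter,A,2,,muac,0.17,0.43,1.48,0.99
inter,A,1,,triceps_skinfold,0.64,17.6,83.7,0.00
inter,A,2,,triceps_skinfold,0.62,4.61,18.8,0.91
inter,A,1,,waist_circumference,0.14,2.05,2.44,0.97
inter,A,2,,waist_circumference,0.14,2.34,2.78,0.96
inter,B,1,,height,0.05,0.53,0.32,0.99
inter,B,2,,height,0.05,1.91,1.15,0.95
inter,B,1,,weight,0.20,0.50,0.76,0.99
inter,B,2,,weight,0.20,0.42,0.62,0.99
inter,B,1,,muac,0.12,1.30,4.59,0.84
inter,B,2,,muac,0.10,0.76,2.69,0.93
inter,B,1,,triceps_skinfold,0.62,14.3,62.3,0.00
inter,B,2,,triceps_skinfold,0.59,14.4,58.2,0.00
inter,B,1,,waist_circumference,0.07,2.29,2.83,0.82
inter,B,2,,waist_circumference,0.06,1.98,2.33,0.86
intra,A,,1,height,0.04,0.62,0.37,0.99
intra,B,,1,height,0.05,0.53,0.32,0.99
intra,A,,1,weight,0.23,0.84,1.18,0.99
intra,B,,1,weight,0.19,0.66,0.99,0.99
intra,A,,1,muac,0.18,0.35,1.21,0.99
intra,B,,1,muac,0.11,1.66,5.78,0.73
intra,A,,1,triceps_skinfold,0.64,4.06,16.0,0.94
intra,B,,1,triceps_skinfold,0.40,1.09,10.2,0.94
intra,A,,1,waist_circumference,0.14,1.22,1.46,0.99
intra,B,,1,waist_circumference,0.08,1.64,1.95,0.94
intra,A,,2,height,0.05,0.90,0.53,0.99
intra,B,,2,height,0.05,0.52,0.32,0.99
intra,A,,2,weight,0.23,0.51,0.71,0.99
intra,B,,2,weight,0.20,0.58,0.87,0.99
intra,A,,2,muac,0.17,0.51,1.77,0.99
intra,B,,2,muac,0.11,0.36,1.27,0.99
intra,A,,2,triceps_skinfold,0.59,2.65,10.6,0.97
intra,B,,2,triceps_skinfold,0.60,4.67,17.2,0.92
intra,A,,2,waist_circumference,0.14,2.01,2.41,0.97
intra,B,,2,waist_circumference,0.09,3.33,4.08,0.79
intra,A,,3,height,0.05,2.07,1.22,0.94
intra,B,,3,height,0.05,1.00,0.60,0.97
intra,A,,3,weight,0.23,0.65,0.93,0.99
intra,B,,3,weight,0.20,2.26,3.36,0.97
intra,A,,3,muac,0.17,0.49,1.71,0.99
intra,B,,3,muac,0.11,0.69,2.45,0.95
intra,A,,3,triceps_skinfold,0.63,4.92,22.2,0.88
intra,B,,3,triceps_skinfold,0.26,2.75,8.22,0.90
intra,A,,3,waist_circumference,0.15,1.45,1.71,0.99
intra,B,,3,waist_circumference,0.06,2.04,2.49,0.80
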