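instrument,preparation,scatter,math_treatment,constituent,n,mean,sd,sec,r2cal,secv,r2cv,rpd
benchtop,whole,NONE,1441,fat,52,2.48,0.26,0.13,0.77,0.15,0.69,1.78
benchtop,whole,NONE,2551,protein,51,0.77,0.09,0.04,0.81,0.06,0.66,1.71
benchtop,whole,SNV_DT,2551,tpc,54,3.04,0.66,0.61,0.15,0.67,0.03,0.98
benchtop,whole,NONE,0011,ph,54,5.60,0.36,0.21,0.65,0.24,0.58,1.52
benchtop,whole,MSC,0011,ta,53,16.81,3.99,2.73,0.53,2.98,0.46,1.34
benchtop,whole,MSC,2551,fi,55,0.07,0.03,0.02,0.25,0.03,0.07,1.03
benchtop,whole,NONE,1441,dm,55,94.49,0.57,0.26,0.80,0.31,0.72,1.86
benchtop,whole,MSC,2551,ash,54,0.16,0.03,0.01,0.87,0.02,0.51,1.43
portable,whole,MSC,1441,fat,54,2.45,0.27,0.18,0.57,0.21,0.38,1.28
portable,whole,SNV_DT,0011,protein,50,0.78,0.10,0.04,0.83,0.07,0.56,1.49
portable,whole,MSC,2551,tpc,48,3.04,0.60,0.22,0.87,0.40,0.56,1.51
portable,whole,MSC,0011,ph,50,5.56,0.37,0.18,0.76,0.20,0.70,1.83
portable,whole,MSC,1441,ta,55,17.26,4.22,2.77,0.57,3.03,0.48,1.39
portable,whole,NONE,0011,fi,55,0.07,0.03,0.02,0.66,0.02,0.58,1.55
portable,whole,MSC,0011,dm,49,94.50,0.54,0.26,0.77,0.32,0.66,1.72
portable,whole,SNV_DT,0011,ash,53,0.16,0.03,0.02,0.66,0.02,0.45,1.36
benchtop,ground,NONE,1441,fat,56,2.45,0.27,0.11,0.84,0.13,0.76,2.11
benchtop,ground,SNV_DT,0011,protein,54,0.77,0.11,0.02,0.95,0.03,0.91,3.40
benchtop,ground,NONE,2551,tpc,55,3.04,0.65,0.51,0.40,0.59,0.16,1.10
benchtop,ground,MSC,0011,ph,50,5.57,0.37,0.08,0.95,0.13,0.88,2.96
benchtop,ground,NONE,1441,ta,52,16.69,3.86,0.80,0.96,1.43,0.86,2.70
benchtop,ground,NONE,1441,fi,55,1.29,0.50,0.27,0.70,0.38,0.42,1.31
benchtop,ground,MSC,0011,dm,56,94.51,0.59,0.15,0.94,0.18,0.90,3.20
benchtop,ground,MSC,0011,ash,50,0.16,0.03,0.01,0.90,0.01,0.89,2.98
portable,ground,NONE,2551,fat,52,2.45,0.27,0.09,0.88,0.12,0.82,2.34
portable,ground,NONE,0011,protein,53,0.77,0.11,0.04,0.84,0.05,0.79,2.17
portable,ground,MSC,0011,tpc,55,3.04,0.65,0.50,0.42,0.57,0.23,1.14
portable,ground,NONE,1441,ph,53,5.56,0.36,0.11,0.90,0.18,0.74,1.98
portable,ground,NONE,0011,ta,51,17.23,4.07,1.14,0.92,1.76,0.81,2.32
portable,ground,NONE,0011,fi,56,1.29,0.49,0.41,0.33,0.42,0.26,1.17
portable,ground,NONE,0011,dm,54,94.54,0.59,0.25,0.81,0.27,0.79,2.17
portable,ground,NONE,1441,ash,54,0.16,0.03,0.01,0.89,0.01,0.76,2.08
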