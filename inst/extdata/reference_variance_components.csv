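trait,condition,sigma2_gca_line,sigma2_gca_tester,sigma2_sca,sigma2_A,sigma2_D,sigma2_E,H2,h2
GY,drought,110197.54,18193.65,54808.25,274664.01,219233.01,254256.89,0.66,0.37
GY,rainfed,222427.66,216691.81,386696.39,879353.75,1546785.62,325088.02,0.88,0.32
DP,drought,0.54,0.77,0.39,2.58,1.54,0.65,0.86,0.54
DP,rainfed,0.25,0.23,0.38,0.96,1.51,0.40,0.86,0.33
DS,drought,1.55,1.11,0.92,5.41,3.69,1.42,0.87,0.51
DS,rainfed,0.75,0.28,0.78,2.16,2.79,0.48,0.91,0.40
ASI,drought,0.23,0.03,0.11,0.55,0.43,0.67,0.59,0.33
ASI,rainfed,0.01,0.03,0.06,0.07,0.23,0.12,0.72,0.16
PHT,drought,42.81,24.88,17.54,138.87,70.17,73.40,0.74,0.49
PHT,rainfed,27.52,54.32,14.92,158.46,59.67,17.91,0.92,0.67
EHT,drought,13.76,13.84,11.15,55.25,44.61,19.04,0.84,0.46
EHT,rainfed,11.35,18.53,10.85,58.37,43.42,15.03,0.87,0.50
PASP,drought,0.05,0.06,0.08,0.20,0.32,0.28,0.65,0.25
PASP,rainfed,0.04,0.21,0.17,0.46,0.39,0.21,0.80,0.43
EASP,drought,0.11,0.03,0.04,0.29,0.16,0.30,0.60,0.39
EASP,rainfed,0,0.02,0.02,0.03,0.09,0.31,0.26,0.06
HCV,drought,0.24,0.57,0.09,1.56,0.35,0.30,0.87,0.71
HCV,rainfed,0.26,1.41,0.18,3.11,0.70,0.20,0.95,0.77
STGC,drought,0.04,0.14,0.11,0.34,0.43,0.27,0.74,0.33
EPP,drought,0,0,0,0.01,0.01,0.01,0.65,0.37
EPP,rainfed,0,0,0,0,0.01,0,0.74,0.17
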