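trait,condition,source,df,mean_square
GY,drought,E,1,16953301.13
GY,drought,REP(E),2,9174207.52
GY,drought,GENOTYPES,179,1530491.13
GY,drought,LINE (GCA Line),35,3246398.69
GY,drought,TESTER (GCA Tester),4,3662333.70
GY,drought,LINE x TESTER (SCA),140,1042447.91
GY,drought,GENOTYPES x E,179,920121.23
GY,drought,GCA LINE x E,35,1073615.32
GY,drought,GCA TESTER x E,4,2057867.95
GY,drought,LINE x TESTER x E,140,849240.66
GY,drought,Residuals,306,823214.9
GY,rainfed,E,1,114277177.06
GY,rainfed,REP(E),2,2980943.84
GY,rainfed,GENOTYPES,179,4209073.7
GY,rainfed,LINE (GCA Line),35,7090612.65
GY,rainfed,TESTER (GCA Tester),4,33845679.66
GY,rainfed,LINE x TESTER (SCA),140,2642059.35
GY,rainfed,GENOTYPES x E,179,1197812.93
GY,rainfed,GCA LINE x E,35,1658989.67
GY,rainfed,GCA TESTER x E,4,2948088.14
GY,rainfed,LINE x TESTER x E,140,1032510.89
GY,rainfed,Residuals,306,1095273.8
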