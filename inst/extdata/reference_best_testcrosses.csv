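condition,genotype,role,GY
drought,TZEEIOR 509 x TZEEIOR 197,testcross,4044.2
drought,TZEEIOR 510 x TZEEIOR 30,testcross,3805.5
drought,TZEEIOR 458 x TZEEIOR 197,testcross,3643
drought,TZEEIOR 314 x TZEEIOR 97,testcross,3604.2
drought,TZEEIOR 510 x TZEEIOR 97,testcross,3569
drought,TZEEIOR 536 x TZEEIOR 30,testcross,3498.1
drought,TZEEIOR 384 x TZEEIOR 30,testcross,3415
drought,TZEEIOR 526 x TZEEIOR 97,testcross,3318.8
drought,TZEEIOR 510 x TZEEIOR 249,testcross,3294.8
drought,TZEEIOR 540 x TZEEIOR 30,testcross,3261.2
drought,TZEEIOR 525 x TZEEIOR 30,testcross,3217.1
drought,TZEEIOR 321 x TZEEIOR 249,testcross,3207.9
drought,TZEEIOR 321 x TZEEIOR 197,testcross,3116.3
drought,TZEEIOR 509 x TZEEIOR 30,testcross,3097
drought,TZEEIOR 479 x TZEEIOR 197,testcross,3073.8
drought,TZEEIOR 523 x TZEEIOR 97,testcross,3054.1
drought,TZEEI 79 x TZEEI 82,check,3015.2
rainfed,TZEEIOR 509 x TZEEIOR 197,testcross,7455
rainfed,BEST COMMERCIAL CHECK,check,5732
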