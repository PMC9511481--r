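compound,pathway,ec50_nM,ec50_lo_nM,ec50_hi_nM,emax_pct,emax_lo_pct,emax_hi_pct,nd,beta_factor
serotonin,barr2,661,415,1025,77.4,71.7,83.4,FALSE,0.550
serotonin,miniGq,1672,728,4550,49.3,41.3,60.4,FALSE,0.550
LSD,barr2,5.19,3.20,8.25,99.9,93.7,106,FALSE,0
LSD,miniGq,5.38,2.85,9.81,99.5,91.6,108,FALSE,0
4a,barr2,172,74.8,443,89.8,75.8,108,FALSE,NA
4a,miniGq,154,NA,NA,21.0,NA,NA,TRUE,NA
4b,barr2,81.9,52.6,126,106,97.5,114,FALSE,0.565
4b,miniGq,112,40.1,327,44.7,36.9,53.9,FALSE,0.565
6a,barr2,37.7,23.3,59.9,114,105,123,FALSE,0.733
6a,miniGq,137,76.2,247,70.3,62.2,78.9,FALSE,0.733
6c,barr2,661,504,853,86.6,81.5,92.0,FALSE,0.731
6c,miniGq,1126,253,3869,20.4,14.1,30.3,FALSE,0.731
6e,barr2,939,614,1388,68.2,62.6,74.3,FALSE,NA
6e,miniGq,2064,NA,NA,12.9,NA,NA,TRUE,NA
6f,barr2,1025,673,1517,90.8,81.9,101,FALSE,NA
6f,miniGq,1653,NA,NA,13.8,NA,NA,TRUE,NA
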