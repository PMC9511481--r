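compound,pathway,ec50_nM,ec50_lo_nM,ec50_hi_nM,emax_pct,emax_lo_pct,emax_hi_pct,nd,beta_factor
serotonin,barr2,12.1,8.52,17.4,110,105,115,FALSE,0.576
serotonin,miniGq,130,63.3,270,222,197,249,FALSE,0.576
LSD,barr2,12.9,8.45,19.7,99.7,93.6,106,FALSE,0
LSD,miniGq,13.2,6.81,25.6,100,91.0,110,FALSE,0
4a,barr2,11.1,7.65,16.2,112,105,118,FALSE,1.240
4a,miniGq,48.8,13.0,157,28.0,22.1,34.7,FALSE,1.240
4b,barr2,11.1,7.59,16.3,113,106,120,FALSE,1.100
4b,miniGq,44.4,19.1,94.6,38.8,34.0,44.3,FALSE,1.100
4c,barr2,28.6,18.9,43.3,96.6,90.4,103,FALSE,0.279
4c,miniGq,23.0,12.0,44.6,48.7,44.0,53.7,FALSE,0.279
4d,barr2,132,108,161,121,115,126,FALSE,0.558
4d,miniGq,174,80.9,423,47.7,40.4,57.5,FALSE,0.558
6a,barr2,2.75,1.73,4.40,150,141,160,FALSE,0.619
6a,miniGq,8.59,3.87,18.1,123,110,136,FALSE,0.619
6b,barr2,1.93,1.17,3.28,161,151,171,FALSE,0.526
6b,miniGq,6.71,3.82,11.4,159,148,170,FALSE,0.526
6c,barr2,53.2,36.8,75.7,114,107,121,FALSE,0.669
6c,miniGq,168,77.7,363,72.5,62.8,82.9,FALSE,0.669
6d,barr2,17.0,10.4,28.2,114,106,123,FALSE,0.638
6d,miniGq,45.1,14.5,128,83.0,67.1,100,FALSE,0.638
6e,barr2,84.5,64.0,111,106,101,112,FALSE,1.250
6e,miniGq,301,46.1,1764,22.5,16.4,30.3,FALSE,1.250
6f,barr2,108,68.6,169,82.9,75.9,90.2,FALSE,NA
6f,miniGq,631,NA,NA,18.0,NA,NA,TRUE,NA
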