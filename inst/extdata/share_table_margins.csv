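gender,block,level,count,percent
F,education,low,12082,28.8
F,education,medium,22272,53.1
F,education,high,7588,18.1
F,education,total,41942,100
F,cohort,1920-1939,13973,33.3
F,cohort,1940-1949,13271,31.6
F,cohort,1950-1962,14698,35.1
F,cohort,total,41942,100
F,region,central,17415,41.5
F,region,northern,5113,12.2
F,region,southern,9174,21.9
F,region,eastern,10240,24.4
F,region,total,41942,100
F,participation,mean,NA,3.76
M,education,low,8101,23.4
M,education,medium,18581,53.7
M,education,high,7928,22.9
M,education,total,34610,100
M,cohort,1920-1939,11287,32.6
M,cohort,1940-1949,11603,33.5
M,cohort,1950-1962,11720,33.9
M,cohort,total,34605,100
M,region,central,14661,42.3
M,region,northern,4521,13.1
M,region,southern,7919,22.9
M,region,eastern,7509,21.7
M,region,total,34610,100
M,participation,mean,NA,3.69
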