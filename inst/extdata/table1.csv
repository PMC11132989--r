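chimpanzee,group,n_observations,acquired,observation_time_h,rate_of_observation,n_solves,trained
BJ,1,205,0,71.38,2.87,0,FALSE
Bob,1,13,0,71.38,0.18,0,FALSE
Booboo,1,0,0,71.38,0,0,FALSE
Brenda,1,56,0,71.38,0.78,0,FALSE
Chrissy,1,21,1,28.99,0.72,333,FALSE
Genny,1,24,0,71.38,0.34,0,FALSE
Gerard,1,0,0,71.38,0,0,FALSE
Girly,1,0,0,71.38,0,0,FALSE
Gonzaga,1,99,0,71.38,1.39,0,FALSE
Ilse,1,32,0,71.38,0.45,0,FALSE
Ingrid,1,13,0,71.38,0.18,0,FALSE
Innocentia,1,44,0,71.38,0.62,0,FALSE
Irene,1,153,0,71.38,2.14,0,FALSE
Pal,1,1,0,71.38,0.01,0,FALSE
Rachel,1,9,1,2.32,3.88,926,FALSE
Regina,1,166,1,45.77,3.63,1048,FALSE
Renate,1,406,0,71.38,5.69,0,FALSE
Rita,1,NA,NA,NA,NA,1970,TRUE
Rusty,1,252,1,49.17,5.12,1,FALSE
Tara,1,3,0,71.38,0.04,0,FALSE
Tobar,1,7,0,71.38,0.1,0,FALSE
Carol,2,17,0,71.38,0.24,0,FALSE
Charity,2,209,1,69.38,3.01,23,FALSE
Claire,2,0,0,71.38,0,0,FALSE
Coco,2,3,0,71.38,0.04,0,FALSE
Daisey,2,75,0,71.38,1.05,0,FALSE
Danny,2,43,1,71.38,9.85,3,FALSE
David,2,0,0,71.38,0,0,FALSE
Debbie,2,13,0,71.38,0.18,0,FALSE
Diana,2,93,1,36.11,2.58,377,FALSE
Dizzy,2,188,0,71.38,2.63,0,FALSE
Dolly,2,19,1,29.2,0.65,1381,FALSE
Donna,2,25,0,71.38,0.35,0,FALSE
Dora,2,33,0,71.38,0.46,0,FALSE
Doug,2,0,0,71.38,0,0,FALSE
Jacky,2,239,0,71.38,3.35,0,FALSE
Jane,2,19,0,71.38,0.27,0,FALSE
John,2,174,0,71.38,2.44,0,FALSE
Jones,2,274,0,71.38,3.84,0,FALSE
Judy,2,135,0,71.38,1.89,0,FALSE
LittleJenkins,2,49,1,50.4,0.97,232,FALSE
Maggie,2,289,0,71.38,4.05,0,FALSE
Martin,2,123,1,54.63,1.85,1,FALSE
Mary,2,59,0,71.38,0.83,0,FALSE
Masya,2,13,0,71.38,0.18,0,FALSE
Max,2,124,0,71.38,1.74,0,FALSE
Maxine,2,31,0,71.38,0.43,0,FALSE
May,2,301,1,69.38,4.47,3,FALSE
Mikey,2,41,0,71.38,0.57,0,FALSE
Misha,2,43,0,71.38,0.6,0,FALSE
Moyo,2,39,0,71.38,0.55,0,FALSE
Nikkie,2,32,1,49.15,0.65,213,FALSE
Nina,2,8,0,71.38,0.11,0,FALSE
Noel,2,14,0,71.38,0.2,0,FALSE
Pan,2,0,0,71.38,0,0,FALSE
Pippa,2,NA,NA,NA,NA,3453,TRUE
Tess,2,14,1,54.78,0.33,179,FALSE
Tilly,2,16,1,38.35,0.42,159,FALSE
Trixie,2,11,0,71.38,0.15,0,FALSE
Violet,2,38,0,71.38,0.53,0,FALSE
Vis,2,25,0,71.38,0.35,0,FALSE
Zsabu,2,9,0,71.38,0.13,0,FALSE
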