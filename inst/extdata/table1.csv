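variable,unit,men_mean,men_sd,women_mean,women_sd
n,count,62,NA,80,NA
age,years,53,11,53,10
bmi,kg/m2,32.5,3.9,32.3,5.4
waist,cm,111.5,9.8,102.7,12.1
fg,mmol/L,6.4,1.7,6.3,1.9
tg,mmol/L,2.4,1.9,1.9,0.9
hdl,mmol/L,1.1,0.3,1.4,0.4
sbp,mmHg,149,18,144,19
dbp,mmHg,87,11,83,9
previous_mi,percent,13,NA,2,NA
diabetes,percent,26,NA,22,NA
smoking,percent,14,NA,32,NA
physical_activity,percent,51,NA,52,NA
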