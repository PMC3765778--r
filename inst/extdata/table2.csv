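sex,level,variable,start,m12,diff
M,low,n,4,NA,NA
M,medium,n,19,NA,NA
M,high,n,39,NA,NA
F,low,n,37,NA,NA
F,medium,n,28,NA,NA
F,high,n,15,NA,NA
M,low,age,46,NA,NA
M,medium,age,54,NA,NA
M,high,age,53,NA,NA
F,low,age,52,NA,NA
F,medium,age,55,NA,NA
F,high,age,55,NA,NA
M,low,bmi,28.3,27.2,-1.1
M,medium,bmi,33.0,32.6,-0.4
M,high,bmi,32.6,32.2,-0.4
F,low,bmi,30.4,29.6,-0.8
F,medium,bmi,33.1,32.0,-1.1
F,high,bmi,35.3,34.7,-0.7
M,low,waist,98,93,-5
M,medium,waist,111,109,-2
M,high,waist,113,110,-3
F,low,waist,98,94,-4
F,medium,waist,104,101,-3
F,high,waist,111,104,-7
M,low,fg,5.9,6.1,0.2
M,medium,fg,5.7,5.6,-0.1
M,high,fg,6.8,6.5,-0.3
F,low,fg,5.5,5.4,-0.1
F,medium,fg,6.7,6.5,-0.2
F,high,fg,7.7,7.1,-0.6
M,low,tg,1.1,0.9,-0.2
M,medium,tg,1.4,1.6,-0.2
M,high,tg,3.0,3.1,-0.1
F,low,tg,1.4,1.3,-0.1
F,medium,tg,2.2,2.0,-0.2
F,high,tg,2.6,2.4,-0.2
M,low,hdl,1.4,1.6,0.2
M,medium,hdl,1.2,1.3,0.1
M,high,hdl,1.0,1.1,0.1
F,low,hdl,1.5,1.6,0.1
F,medium,hdl,1.3,1.4,0.1
F,high,hdl,1.2,1.3,0.1
M,low,chol,4.3,4.2,-0.1
M,medium,chol,4.5,4.3,-0.2
M,high,chol,4.4,4.3,-0.1
F,low,chol,5.0,4.9,-0.1
F,medium,chol,4.8,5.0,-0.2
F,high,chol,4.7,4.4,-0.3
M,low,sbp,140,132,-8
M,medium,sbp,148,143,-5
M,high,sbp,150,141,-9
F,low,sbp,137,137,0
F,medium,sbp,147,140,-7
F,high,sbp,154,144,-10
M,low,dbp,83,80,-3
M,medium,dbp,86,85,-1
M,high,dbp,88,84,-4
F,low,dbp,80,78,-2
F,medium,dbp,86,84,-2
F,high,dbp,86,81,-5
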