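sex,level,measure,start,m12,diff
M,low,yll,6.31,6.05,-0.26
M,medium,yll,6.06,5.75,-0.31
M,high,yll,9.62,9.32,-0.30
F,low,yll,4.17,3.94,-0.22
F,medium,yll,7.64,7.36,-0.28
F,high,yll,9.49,9.15,-0.35
M,low,qaly,13.92,13.97,0.05
M,medium,qaly,10.79,10.93,0.14
M,high,qaly,9.89,10.01,0.12
F,low,qaly,12.44,12.53,0.09
F,medium,qaly,9.95,10.08,0.13
F,high,qaly,9.29,9.37,0.08
M,low,cost_societal,56443,53998,-2446
M,medium,cost_societal,52865,49902,-2963
M,high,cost_societal,70948,67727,-3221
F,low,cost_societal,48979,46830,-2149
F,medium,cost_societal,69191,66850,-2341
F,high,cost_societal,71887,70532,-1354
M,low,cost_healthcare,37314,35616,-1698
M,medium,cost_healthcare,37289,35738,-1551
M,high,cost_healthcare,50093,48232,-1862
F,low,cost_healthcare,35023,33727,-1295
F,medium,cost_healthcare,51911,50612,-1299
F,high,cost_healthcare,53873,53114,-759
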