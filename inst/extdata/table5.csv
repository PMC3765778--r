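perspective,sex,level,delta_qaly,net_cost,cost_per_qaly
societal,M,low,0.05,364,7276
societal,M,medium,0.14,<0,<0
societal,M,high,0.12,<0,<0
societal,F,low,0.09,660,7337
societal,F,medium,0.13,469,3608
societal,F,high,0.08,1455,18191
healthcare,M,low,0.05,561,11213
healthcare,M,medium,0.14,707,5052
healthcare,M,high,0.12,397,3305
healthcare,F,low,0.09,963,10698
healthcare,F,medium,0.13,959,7379
healthcare,F,high,0.08,1499,18739
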