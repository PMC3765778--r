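description: 'Default risk-engine parameter set: age-banded annual baseline hazards
  (Gompertz-shaped), proportional-hazards coefficients inspired by published CVD/T2D
  risk scores, Swedish-style life table and QoL norms. Intended to be calibrated against
  group-level YLL ranges.'
age_band_starts:
- 30.0
- 35.0
- 40.0
- 45.0
- 50.0
- 55.0
- 60.0
- 65.0
- 70.0
- 75.0
- 80.0
baseline_hazards:
  t2d_onset:
    M:
    - 0.002279
    - 0.002583
    - 0.002926
    - 0.003316
    - 0.003758
    - 0.004258
    - 0.004825
    - 0.005467
    - 0.006195
    - 0.00702
    - 0.007955
    F:
    - 0.002051
    - 0.002324
    - 0.002634
    - 0.002985
    - 0.003382
    - 0.003832
    - 0.004342
    - 0.004921
    - 0.005576
    - 0.006318
    - 0.007159
  cvd_onset:
    M:
    - 0.000725
    - 0.001028
    - 0.001459
    - 0.00207
    - 0.002938
    - 0.004169
    - 0.005917
    - 0.008396
    - 0.011915
    - 0.016908
    - 0.023993
    F:
    - 0.000393
    - 0.000558
    - 0.000792
    - 0.001124
    - 0.001595
    - 0.002263
    - 0.003212
    - 0.004558
    - 0.006468
    - 0.009178
    - 0.013025
  t2d_compl:
    M:
    - 0.015941
    - 0.017617
    - 0.01947
    - 0.021518
    - 0.023781
    - 0.026282
    - 0.029046
    - 0.032101
    - 0.035477
    - 0.039208
    - 0.043331
    F:
    - 0.015941
    - 0.017617
    - 0.01947
    - 0.021518
    - 0.023781
    - 0.026282
    - 0.029046
    - 0.032101
    - 0.035477
    - 0.039208
    - 0.043331
  t2d_cvd_onset:
    M:
    - 0.001594
    - 0.002262
    - 0.00321
    - 0.004555
    - 0.006464
    - 0.009173
    - 0.013017
    - 0.018471
    - 0.026212
    - 0.037197
    - 0.052785
    F:
    - 0.000869
    - 0.001234
    - 0.001751
    - 0.002485
    - 0.003526
    - 0.005003
    - 0.0071
    - 0.010075
    - 0.014297
    - 0.020289
    - 0.028792
  t2d_death:
    M:
    - 0.000518
    - 0.0007
    - 0.000945
    - 0.001275
    - 0.001721
    - 0.002324
    - 0.003137
    - 0.004234
    - 0.005715
    - 0.007715
    - 0.010414
    F:
    - 0.000467
    - 0.00063
    - 0.00085
    - 0.001148
    - 0.001549
    - 0.002091
    - 0.002823
    - 0.003811
    - 0.005144
    - 0.006943
    - 0.009373
  compl_cvd:
    M:
    - 0.002029
    - 0.002879
    - 0.004085
    - 0.005797
    - 0.008227
    - 0.011674
    - 0.016566
    - 0.023509
    - 0.033361
    - 0.047341
    - 0.06718
    F:
    - 0.001097
    - 0.001557
    - 0.002209
    - 0.003135
    - 0.004449
    - 0.006314
    - 0.008959
    - 0.012714
    - 0.018042
    - 0.025603
    - 0.036332
  compl_death:
    M:
    - 0.003247
    - 0.004169
    - 0.005353
    - 0.006873
    - 0.008825
    - 0.011331
    - 0.01455
    - 0.018682
    - 0.023989
    - 0.030802
    - 0.039551
    F:
    - 0.002922
    - 0.003752
    - 0.004817
    - 0.006186
    - 0.007942
    - 0.010198
    - 0.013095
    - 0.016814
    - 0.02159
    - 0.027722
    - 0.035596
  cvd_t2d:
    M:
    - 0.003191
    - 0.003616
    - 0.004097
    - 0.004643
    - 0.005261
    - 0.005961
    - 0.006755
    - 0.007654
    - 0.008673
    - 0.009828
    - 0.011137
    F:
    - 0.002849
    - 0.003228
    - 0.003658
    - 0.004145
    - 0.004697
    - 0.005322
    - 0.006031
    - 0.006834
    - 0.007744
    - 0.008775
    - 0.009944
  cvd_death:
    M:
    - 0.005844
    - 0.007504
    - 0.009635
    - 0.012371
    - 0.015885
    - 0.020397
    - 0.02619
    - 0.033628
    - 0.04318
    - 0.055444
    - 0.071191
    F:
    - 0.005194
    - 0.00667
    - 0.008564
    - 0.010997
    - 0.01412
    - 0.01813
    - 0.02328
    - 0.029892
    - 0.038382
    - 0.049283
    - 0.063281
  t2d_cvd_death:
    M:
    - 0.012986
    - 0.016674
    - 0.02141
    - 0.027492
    - 0.0353
    - 0.045326
    - 0.0582
    - 0.07473
    - 0.095955
    - 0.123209
    - 0.158203
    F:
    - 0.011687
    - 0.015007
    - 0.019269
    - 0.024742
    - 0.03177
    - 0.040793
    - 0.05238
    - 0.067257
    - 0.08636
    - 0.110888
    - 0.142383
coefficients:
  t2d_onset:
    fg: 0.5
    bmi: 0.06
    waist: 0.012
    tg: 0.08
    hdl: -0.35
  cvd_onset:
    sbp: 0.022
    chol: 0.2
    hdl: -0.5
    smoker: 0.55
    fg: 0.07
    bmi: 0.02
  t2d_compl:
    fg: 0.22
    sbp: 0.012
  t2d_cvd_onset:
    sbp: 0.022
    chol: 0.2
    hdl: -0.5
    smoker: 0.55
    fg: 0.07
    bmi: 0.02
  t2d_death:
    fg: 0.12
  compl_cvd:
    sbp: 0.022
    chol: 0.2
    hdl: -0.5
    smoker: 0.55
    fg: 0.07
    bmi: 0.02
  compl_death:
    fg: 0.08
  cvd_t2d:
    fg: 0.5
    bmi: 0.06
    waist: 0.012
    tg: 0.08
    hdl: -0.35
  cvd_death:
    sbp: 0.01
    smoker: 0.3
  t2d_cvd_death:
    sbp: 0.008
    fg: 0.08
reference_profile:
  waist: 94.0
  bmi: 27.0
  fg: 5.3
  tg: 1.5
  hdl: 1.3
  chol: 5.0
  sbp: 125.0
  dbp: 80.0
  smoker: 0.0
other_cause_mortality:
  M:
  - 0.000618
  - 0.000946
  - 0.001446
  - 0.002212
  - 0.003384
  - 0.005176
  - 0.007917
  - 0.01211
  - 0.018524
  - 0.028334
  - 0.043339
  F:
  - 0.000559
  - 0.000856
  - 0.001309
  - 0.002002
  - 0.003062
  - 0.004683
  - 0.007163
  - 0.010957
  - 0.016759
  - 0.025635
  - 0.039211
qol_population:
- 0.89
- 0.88
- 0.87
- 0.85
- 0.84
- 0.82
- 0.81
- 0.8
- 0.78
- 0.76
- 0.74
qol_multipliers:
  WELL: 1.0
  T2D: 0.88
  T2D_COMPL: 0.72
  CVD: 0.78
  T2D_CVD: 0.65
state_costs:
  societal:
    T2D: 2600.0
    T2D_COMPL: 9500.0
    CVD: 7500.0
    T2D_CVD: 12500.0
  healthcare:
    T2D: 1900.0
    T2D_COMPL: 6500.0
    CVD: 5000.0
    T2D_CVD: 8500.0
termination_age: 85.0
cycle_length: 1.0
hazard_scale: 1.0
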