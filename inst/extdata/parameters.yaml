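meta:
  schema: exeCEA-parameters
  schema_version: 1
economics:
  discount_rate: 0.03
  discount_rate_low: 0.0
  discount_rate_high: 0.05
  horizon_cycles: 50
  cycle_length: 1.0
  cohort_size: 1000.0
  entry_age: 40.0
  dm_prevalence_at_entry: 0.0605
  wtp_gdp: 839558.0
  rate_conversion: exponential
  reward_timing: start
  dm_cost_basis: matched
  pddm_includes_dm_medical: no
  dm_utility_decline_mode: model_time
  pddm_lambda3: product
  scenario2_mode: multiplier
incidence:
  pd:
    lower:
    - 40.0
    - 50.0
    - 60.0
    - 70.0
    - 80.0
    upper:
    - 50.0
    - 60.0
    - 70.0
    - 80.0
    - Inf
    value:
    - 0.0
    - 0.000211
    - 0.000995
    - 0.003005
    - 0.003699
    low:
    - .na.real
    - 0.000193
    - 0.000773
    - 0.002577
    - 0.00328
    high:
    - .na.real
    - 0.000229
    - 0.001218
    - 0.003435
    - 0.004118
  dm:
    lower:
    - 40.0
    - 50.0
    - 60.0
    - 70.0
    - 80.0
    upper:
    - 50.0
    - 60.0
    - 70.0
    - 80.0
    - Inf
    value:
    - 0.00964
    - 0.00964
    - 0.01906
    - 0.01906
    - 0.01637
    low:
    - 0.00911
    - 0.00911
    - 0.01699
    - 0.01699
    - 0.01419
    high:
    - 0.01017
    - 0.01017
    - 0.02112
    - 0.02112
    - 0.01854
  pd_dm:
    lower:
    - 40.0
    - 50.0
    - 60.0
    - 70.0
    - 80.0
    upper:
    - 50.0
    - 60.0
    - 70.0
    - 80.0
    - Inf
    value:
    - 0.0
    - 0.000464
    - 0.001542
    - 0.004658
    - 0.005733
    low:
    - .na.real
    - 0.000371
    - 0.001453
    - 0.004387
    - 0.005401
    high:
    - .na.real
    - 0.000578
    - 0.001711
    - 0.005169
    - 0.006362
mortality:
  dm:
    lower:
    - 40.0
    - 50.0
    - 60.0
    - 70.0
    - 75.0
    upper:
    - 50.0
    - 60.0
    - 70.0
    - 75.0
    - Inf
    value:
    - 0.0151
    - 0.02195
    - 0.03931
    - 0.05288
    - 0.0815
    low:
    - 0.0099
    - 0.0123
    - 0.0273
    - 0.0486
    - 0.0778
    high:
    - 0.0203
    - 0.035
    - 0.0547
    - 0.058
    - 0.0863
  dm_exenatide_printed:
    lower:
    - 40.0
    - 50.0
    - 60.0
    - 70.0
    - 75.0
    upper:
    - 50.0
    - 60.0
    - 70.0
    - 75.0
    - Inf
    value:
    - 0.01329
    - 0.01932
    - 0.03459
    - 0.04653
    - 0.07172
    low:
    - 0.0129
    - 0.0189
    - 0.0338
    - 0.0455
    - 0.0701
    high:
    - 0.0136
    - 0.0198
    - 0.0353
    - 0.0476
    - 0.0734
  other:
    lower:
    - 40.0
    - 50.0
    - 60.0
    - 70.0
    - 80.0
    upper:
    - 50.0
    - 60.0
    - 70.0
    - 80.0
    - Inf
    value:
    - 0.00266
    - 0.00507
    - 0.01028
    - 0.02677
    - 0.05722
    low:
    - 0.0017
    - 0.0038
    - 0.007
    - 0.0164
    - 0.0432
    high:
    - 0.0035
    - 0.0065
    - 0.0148
    - 0.0393
    - 0.0628
  pd_stage:
    stage:
    - 1
    - 2
    - 3
    - 4
    value:
    - 0.01
    - 0.048
    - 0.08
    - 0.199
    low:
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    high:
    - .na.real
    - .na.real
    - .na.real
    - .na.real
rates:
  pd:
  - 0.3237
  - 0.068
  - 0.3192
  pd_dm:
  - 0.4369
  - 0.1462
  - 0.3192
  treated_printed:
    pd:
    - 0.3065
    - 0.0163
    - 0.0658
    pd_dm:
    - 0.4137
    - 0.0349
    - 0.021
effects:
  multipliers:
  - 0.947
  - 0.239
  - 0.206
  multipliers_printed:
    id:
    - m1
    - m2
    - m3
    value:
    - 0.981
    - 0.245
    - 0.214
    low:
    - 0.95
    - 0.2
    - 0.17
    high:
    - 0.99
    - 0.32
    - 0.28
  dm_mortality_factor: 0.88
  dm_mortality_factor_low: 0.86
  dm_mortality_factor_high: 0.9
  dm_utility_increment: 0.08
  dm_utility_increment_low: 0.06
  dm_utility_increment_high: 0.1
  pd_incidence_reduction: 0.0
costs:
  pd_medical:
    stage:
    - 1
    - 2
    - 3
    - 4
    value:
    - 21821.900000000001
    - 69074.199999999997
    - 71969.300000000003
    - 133558.100000000006
    low:
    - .na.real
    - 17470.5
    - 22218.5
    - 50890.599999999999
    high:
    - .na.real
    - 254268.399999999994
    - 152150.799999999988
    - 172994.600000000006
  pddm_medical:
    stage:
    - 1
    - 2
    - 3
    - 4
    value:
    - 21821.900000000001
    - 90217.100000000006
    - 77079.100000000006
    - 148740.899999999994
    low:
    - .na.real
    - 24685.299999999999
    - 43927.400000000001
    - .na.real
    high:
    - .na.real
    - 264341.0
    - 123334.5
    - .na.real
  home_care:
    stage:
    - 1
    - 2
    - 3
    - 4
    value:
    - 0.0
    - 0.0
    - 22220.0
    - 22220.0
    low:
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    high:
    - .na.real
    - .na.real
    - .na.real
    - .na.real
  pd_productivity:
    stage:
    - 1
    - 2
    - 3
    - 4
    value:
    - 17261.200000000001
    - 52185.099999999999
    - 95538.899999999994
    - 54593.699999999997
    low:
    - 5218.5
    - 40142.400000000001
    - 83496.199999999997
    - 42550.900000000001
    high:
    - 29304.0
    - 64227.800000000003
    - 107581.600000000006
    - 66636.399999999994
  dm_medical:
    lower:
    - 40.0
    - 50.0
    - 60.0
    - 70.0
    - 80.0
    upper:
    - 50.0
    - 60.0
    - 70.0
    - 80.0
    - Inf
    value:
    - 43903.599999999999
    - 58903.599999999999
    - 73903.600000000006
    - 88903.600000000006
    - 103903.600000000006
    low:
    - 39887.800000000003
    - 54887.800000000003
    - 69887.800000000003
    - 84887.800000000003
    - 99887.800000000003
    high:
    - 47919.400000000001
    - 62919.400000000001
    - 77919.399999999994
    - 92919.399999999994
    - 107919.399999999994
  dm_productivity:
    lower:
    - 40.0
    - 50.0
    - 60.0
    - 70.0
    upper:
    - 50.0
    - 60.0
    - 70.0
    - Inf
    value:
    - 635049.0
    - 605055.599999999977
    - 481893.0
    - 0.0
    low:
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    high:
    - .na.real
    - .na.real
    - .na.real
    - .na.real
  exenatide_annual: 33926.800000000003
utilities:
  normal:
    lower:
    - 40.0
    - 65.0
    upper:
    - 65.0
    - Inf
    value:
    - 0.92
    - 0.84
    low:
    - 0.74
    - 0.39
    high:
    - 1.0
    - 1.0
  pd:
    stage:
    - 1
    - 2
    - 3
    - 4
    value:
    - 0.708
    - 0.678
    - 0.622
    - 0.499
    low:
    - 0.638
    - 0.608
    - 0.552
    - 0.429
    high:
    - 0.778
    - 0.748
    - 0.692
    - 0.569
  dm_decrement: 0.04
  dm_decrement_low: 0.0352
  dm_decrement_high: 0.0448
  dm_annual_decline: 0.003
  dm_annual_decline_low: 0.00214
  dm_annual_decline_high: 0.00387

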