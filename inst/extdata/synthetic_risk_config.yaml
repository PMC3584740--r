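curves:
- cause: oral cavity and pharynx cancer
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.2663353
  extension_policy: linearize_then_cap
  beta1: 0.0075271
- cause: esophageal cancer
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.0634655
  extension_policy: linearize_then_cap
  beta1: 0.0055162
- cause: colorectal cancer
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.0597817
  extension_policy: linearize_then_cap
  beta1: 0.0025694
- cause: liver cancer
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.2115272
  extension_policy: linearize_then_cap
  beta1: 0.0048988
- cause: breast cancer
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.0933711
  extension_policy: linearize_then_cap
  beta1: 0.0020397
- cause: epilepsy
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.156763
  extension_policy: linearize_then_cap
  beta1: 0.0060152
- cause: lower respiratory infections
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.1684661
  extension_policy: linearize_then_cap
  beta1: 0.003811
- cause: stroke
  sex: male
  form: log_quadratic
  x_valid_max: 150.0
  rr_former: 1.0641465
  extension_policy: linearize_then_cap
  beta1: -0.0027407
  beta2: 4.1876999e-05
- cause: hypertension
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.1258797
  extension_policy: linearize_then_cap
  beta1: 0.0053077
- cause: liver cirrhosis
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.0009387
  extension_policy: linearize_then_cap
  beta1: 0.0151517
- cause: diabetes
  sex: male
  form: log_quadratic
  x_valid_max: 150.0
  rr_former: 1.2571775
  extension_policy: linearize_then_cap
  beta1: -0.0078354
  beta2: 8.9944296e-05
- cause: tuberculosis
  sex: male
  form: categorical
  x_valid_max: 150.0
  rr_former: 1.2904403
  extension_policy: cap_at_valid_max
  bands:
  - - 0.0
    - 40.0
    - 1.2
  - - 40.0
    - 100.0
    - 2.0
  - - 100.0
    - Inf
    - 3.3
- cause: ischemic heart disease
  sex: male
  form: log_quadratic
  x_valid_max: 150.0
  rr_former: 1.1159491
  extension_policy: linearize_then_cap
  beta1: -0.0108241
  beta2: 5.305404e-05
- cause: motor vehicle accidents
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.0076877
  extension_policy: linearize_then_cap
  beta1: 0.0056848
- cause: suicide
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.2636226
  extension_policy: linearize_then_cap
  beta1: 0.0056848
- cause: other injuries
  sex: male
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.1710163
  extension_policy: linearize_then_cap
  beta1: 0.0056848
- cause: oral cavity and pharynx cancer
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.1182334
  extension_policy: linearize_then_cap
  beta1: 0.0071462
- cause: esophageal cancer
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.2751407
  extension_policy: linearize_then_cap
  beta1: 0.0054441
- cause: colorectal cancer
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.0358035
  extension_policy: linearize_then_cap
  beta1: 0.0018471
- cause: liver cancer
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.2836483
  extension_policy: linearize_then_cap
  beta1: 0.0031716
- cause: breast cancer
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.1989653
  extension_policy: linearize_then_cap
  beta1: 0.0033419
- cause: epilepsy
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.1920321
  extension_policy: linearize_then_cap
  beta1: 0.008022
- cause: lower respiratory infections
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.2040881
  extension_policy: linearize_then_cap
  beta1: 0.0036029
- cause: stroke
  sex: female
  form: log_quadratic
  x_valid_max: 150.0
  rr_former: 1.2043562
  extension_policy: linearize_then_cap
  beta1: -0.0046263
  beta2: 4.0954617e-05
- cause: hypertension
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.2480668
  extension_policy: linearize_then_cap
  beta1: 0.0062875
- cause: liver cirrhosis
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.0812124
  extension_policy: linearize_then_cap
  beta1: 0.0153376
- cause: diabetes
  sex: female
  form: log_quadratic
  x_valid_max: 150.0
  rr_former: 1.0501615
  extension_policy: linearize_then_cap
  beta1: -0.0069167
  beta2: 6.6813269e-05
- cause: tuberculosis
  sex: female
  form: categorical
  x_valid_max: 150.0
  rr_former: 1.0592076
  extension_policy: cap_at_valid_max
  bands:
  - - 0.0
    - 40.0
    - 1.2
  - - 40.0
    - 100.0
    - 2.0
  - - 100.0
    - Inf
    - 3.3
- cause: ischemic heart disease
  sex: female
  form: log_quadratic
  x_valid_max: 150.0
  rr_former: 1.2432537
  extension_policy: linearize_then_cap
  beta1: -0.0093956
  beta2: 5.9885674e-05
- cause: motor vehicle accidents
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.1180791
  extension_policy: linearize_then_cap
  beta1: 0.0040383
- cause: suicide
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.0227262
  extension_policy: linearize_then_cap
  beta1: 0.0040383
- cause: other injuries
  sex: female
  form: log_linear
  x_valid_max: 150.0
  rr_former: 1.1125042
  extension_policy: linearize_then_cap
  beta1: 0.0040383
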