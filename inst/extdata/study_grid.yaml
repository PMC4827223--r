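# Default simulation study: 2 outcome families x 3 association shapes
# x 2 treatment-effect settings (null, calibrated 80%-power effect).
# Top-level values are defaults applied to every scenario.
reps: 5000
alpha_level: 0.05
scenarios:
  - {outcome_family: continuous, shape: linear,       beta_trt: 0,          seed: 101}
  - {outcome_family: continuous, shape: linear,       beta_trt: calibrated, seed: 102}
  - {outcome_family: continuous, shape: monotonic,    beta_trt: 0,          seed: 103}
  - {outcome_family: continuous, shape: monotonic,    beta_trt: calibrated, seed: 104}
  - {outcome_family: continuous, shape: nonmonotonic, beta_trt: 0,          seed: 105}
  - {outcome_family: continuous, shape: nonmonotonic, beta_trt: calibrated, seed: 106}
  - {outcome_family: binary,     shape: linear,       beta_trt: 0,          seed: 107}
  - {outcome_family: binary,     shape: linear,       beta_trt: calibrated, seed: 108}
  - {outcome_family: binary,     shape: monotonic,    beta_trt: 0,          seed: 109}
  - {outcome_family: binary,     shape: monotonic,    beta_trt: calibrated, seed: 110}
  - {outcome_family: binary,     shape: nonmonotonic, beta_trt: 0,          seed: 111}
  - {outcome_family: binary,     shape: nonmonotonic, beta_trt: calibrated, seed: 112}
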