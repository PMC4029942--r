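{
  "name": "SE1",
  "description": "Sensor-estimation (best-case) initialization, subject 1: variances estimated from the whole raw recording in post-processing.",
  "f_f0": 1.3,
  "f_s0": 0.3,
  "sigma_trend0": [989.0, 159.2, 1057.7],
  "sigma_noise0": [53.6, 11.2, 64.2],
  "sigma_heart0": [1112.1, 195.8, 1605.8],
  "sigma_resp0": [10195.7, 1114.4, 8498.0],
  "scal_f": [1.0, 0.1, 0.1],
  "scal_s": [0.1, 1.0, 1.0]
}
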