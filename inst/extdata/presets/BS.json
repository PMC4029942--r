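{
  "name": "BS",
  "description": "Bad settings: a deliberately misconfigured filter (noise variances far too high, signal variances far too low) used as the worst-case scenario.",
  "f_f0": 1.0,
  "f_s0": 0.1,
  "sigma_trend0": [1.0, 1.0, 1.0],
  "sigma_noise0": [1000.0, 1000.0, 1000.0],
  "sigma_heart0": [1.0, 1.0, 1.0],
  "sigma_resp0": [1.0, 1.0, 1.0],
  "scal_f": [1.0, 0.1, 0.1],
  "scal_s": [0.1, 1.0, 1.0]
}
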