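{
  "name": "DS",
  "description": "Default settings expected to work adequately in most cases.",
  "f_f0": 1.5,
  "f_s0": 0.1,
  "sigma_trend0": [100.0, 100.0, 100.0],
  "sigma_noise0": [10.0, 10.0, 10.0],
  "sigma_heart0": [100.0, 100.0, 100.0],
  "sigma_resp0": [10000.0, 10000.0, 10000.0],
  "scal_f": [1.0, 0.1, 0.1],
  "scal_s": [0.1, 1.0, 1.0]
}
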