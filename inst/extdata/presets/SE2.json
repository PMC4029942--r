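{
  "name": "SE2",
  "description": "Sensor-estimation (best-case) initialization, subject 2.",
  "f_f0": 1.7,
  "f_s0": 0.2,
  "sigma_trend0": [54.1, 819.9, 1801.5],
  "sigma_noise0": [6.7, 12.2, 15.6],
  "sigma_heart0": [70.1, 198.8, 454.8],
  "sigma_resp0": [191.2, 4137.1, 5846.5],
  "scal_f": [1.0, 0.1, 0.1],
  "scal_s": [0.1, 1.0, 1.0]
}
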