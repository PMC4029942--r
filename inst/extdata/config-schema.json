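{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "akfvitals filter configuration",
  "type": "object",
  "properties": {
    "preset": {"type": "string", "enum": ["SE1", "SE2", "DS", "BS"]},
    "adaptive": {"type": "boolean"},
    "fs": {"type": "number", "exclusiveMinimum": 0},
    "f_f0": {"type": "number", "exclusiveMinimum": 0},
    "f_s0": {"type": "number", "exclusiveMinimum": 0},
    "sigma_trend0": {"$ref": "#/$defs/pos3"},
    "sigma_noise0": {"$ref": "#/$defs/pos3"},
    "sigma_heart0": {"$ref": "#/$defs/pos3"},
    "sigma_resp0": {"$ref": "#/$defs/pos3"},
    "scal_f": {"$ref": "#/$defs/scal3"},
    "scal_s": {"$ref": "#/$defs/scal3"},
    "cadence": {"type": "integer", "minimum": 1},
    "warmup_s": {"type": "number", "minimum": 0},
    "short_window_s": {"type": "number", "exclusiveMinimum": 0},
    "long_window_s": {"type": "number", "exclusiveMinimum": 0},
    "resp_buffer_s": {"type": "number", "exclusiveMinimum": 0},
    "heart_buffer_s": {"type": "number", "exclusiveMinimum": 0},
    "estimate_cutoff_hz": {"type": "number", "exclusiveMinimum": 0},
    "heart_rate_cutoff_hz": {"type": "number", "exclusiveMinimum": 0},
    "resp_rate_cutoff_hz": {"type": "number", "exclusiveMinimum": 0},
    "noise_diff_divisor": {"type": "number", "exclusiveMinimum": 0},
    "heart_std_divisor": {"type": "number", "exclusiveMinimum": 0},
    "noise_floor_factor": {"type": "number", "minimum": 0},
    "heart_band_hz": {"$ref": "#/$defs/band"},
    "resp_band_hz": {"$ref": "#/$defs/band"},
    "heart_min_sep_frac": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
    "resp_min_sep_frac": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
    "heart_swing_frac": {"type": "number", "minimum": 0, "exclusiveMaximum": 1},
    "resp_swing_frac": {"type": "number", "minimum": 0, "exclusiveMaximum": 1},
    "heart_detrend_s": {"type": "number", "minimum": 0},
    "resp_detrend_s": {"type": "number", "minimum": 0},
    "p0_osc_factor": {"type": "number", "exclusiveMinimum": 0}
  },
  "$defs": {
    "pos3": {
      "type": "array", "items": {"type": "number", "exclusiveMinimum": 0},
      "minItems": 3, "maxItems": 3
    },
    "scal3": {
      "type": "array",
      "items": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
      "minItems": 3, "maxItems": 3
    },
    "band": {
      "type": "array", "items": {"type": "number", "exclusiveMinimum": 0},
      "minItems": 2, "maxItems": 2
    }
  }
}
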