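{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "liveqibc QC report",
  "type": "object",
  "required": ["registration"],
  "properties": {
    "registration": {
      "type": "object",
      "required": ["failed", "translation", "n_matched",
                   "n_unmatched_live", "n_unmatched_endpoint"],
      "properties": {
        "failed": {"type": "boolean"},
        "translation": {"type": "array", "items": {"type": "number"},
                        "minItems": 2, "maxItems": 2},
        "n_matched": {"type": "integer", "minimum": 0},
        "n_unmatched_live": {"type": "integer", "minimum": 0},
        "n_unmatched_endpoint": {"type": "integer", "minimum": 0}
      }
    },
    "elution": {
      "type": "object",
      "properties": {
        "pass": {"type": "boolean"},
        "median_residual": {"type": "number"},
        "n_excluded": {"type": "integer"},
        "outliers": {"type": "array", "items": {"type": "integer"}}
      }
    }
  }
}
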