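{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "AtlasFuse fusion report",
  "type": "object",
  "required": ["n_proposals", "atlas_ids", "similarities", "weights",
               "config", "fused_volume_mm3"],
  "properties": {
    "n_proposals": {"type": "integer", "minimum": 1},
    "atlas_ids": {"type": "array", "items": {"type": "string"}},
    "similarities": {
      "type": "array",
      "items": {"type": "number", "minimum": -1.1, "maximum": 1.1}
    },
    "weights": {
      "type": "array",
      "items": {"type": "number", "minimum": 0, "maximum": 1}
    },
    "config": {
      "type": "object",
      "required": ["k_over_s", "margin_mm", "quadrature_nodes"],
      "properties": {
        "k_over_s": {"type": "number", "minimum": 0},
        "margin_mm": {"type": "number", "minimum": 0},
        "quadrature_nodes": {"type": "integer", "minimum": 32}
      }
    },
    "fused_volume_mm3": {"type": "number", "minimum": 0}
  }
}
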