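{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "sefrisk assessment report",
  "type": "object",
  "required": ["n_species", "sef_signal", "srf_signal", "sef_label",
               "srf_label", "quadrant", "correlation", "risk", "filter",
               "settings"],
  "properties": {
    "n_species": {"type": "integer", "minimum": 5},
    "sef_signal": {"type": "object", "required": ["statistic", "n"]},
    "srf_signal": {"type": "object", "required": ["statistic", "n"]},
    "sef_label": {
      "type": "object",
      "required": ["level", "kind", "value"],
      "properties": {
        "level": {"enum": ["none", "weak", "moderate", "strong"]},
        "kind": {"enum": ["lambda", "one_minus_d"]},
        "value": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "srf_label": {"$ref": "#/properties/sef_label"},
    "quadrant": {"enum": ["A", "B", "C", "D"]},
    "correlation": {
      "type": "object",
      "required": ["phylo_r2", "nonphylo_r2", "sign", "quadratic_p"],
      "properties": {
        "phylo_r2": {"type": "number", "minimum": 0, "maximum": 1},
        "nonphylo_r2": {"type": "number", "minimum": 0, "maximum": 1},
        "sign": {"enum": [-1, 0, 1]}
      }
    },
    "risk": {
      "type": "object",
      "required": ["level", "maximum_concern", "strength"],
      "properties": {
        "level": {"enum": ["very_low", "low", "high", "maximum"]},
        "maximum_concern": {"type": "boolean"}
      }
    },
    "filter": {
      "type": "object",
      "required": ["survivors", "sef_before", "sef_after",
                   "pd_retained_fraction", "quantile_used"],
      "properties": {
        "pd_retained_fraction": {"type": "number", "exclusiveMinimum": 0,
                                 "maximum": 1}
      }
    },
    "seed": {"type": ["integer", "null"]},
    "settings": {"type": "object", "required": ["cutpoints", "stage_seeds"]}
  }
}
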