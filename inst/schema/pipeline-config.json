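{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "tscmr pipeline configuration",
  "type": "object",
  "required": ["exposure_path", "outcome_path", "confounder_paths"],
  "additionalProperties": false,
  "properties": {
    "exposure_path": {"type": "string"},
    "outcome_path": {"type": "string"},
    "confounder_paths": {
      "oneOf": [
        {"type": "array", "items": {"type": "string"}, "minItems": 1},
        {"type": "object", "additionalProperties": {"type": "string"},
         "minProperties": 1}
      ]
    },
    "exposure_map": {"$ref": "#/$defs/column_map"},
    "outcome_map": {"$ref": "#/$defs/column_map"},
    "confounder_maps": {
      "type": "array", "items": {"$ref": "#/$defs/column_map"}
    },
    "instruments": {"type": "array", "items": {"type": "string"}},
    "p_threshold": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
    "confounder_p_threshold": {"type": "number", "exclusiveMinimum": 0,
                               "maximum": 1},
    "q_pvalue_threshold": {"type": "number", "exclusiveMinimum": 0,
                           "exclusiveMaximum": 1},
    "palindrome_eaf_window": {"type": "number", "minimum": 0,
                              "exclusiveMaximum": 0.5},
    "n_boot": {"type": "integer", "minimum": 0},
    "seed": {"type": "integer"},
    "out_dir": {"type": "string"}
  },
  "$defs": {
    "column_map": {
      "type": "object",
      "description": "file column name -> standard field (snp_id, effect_allele, other_allele, eaf, beta, se, pval, n)",
      "additionalProperties": {
        "enum": ["snp_id", "effect_allele", "other_allele", "eaf",
                 "beta", "se", "pval", "n"]
      }
    }
  }
}
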