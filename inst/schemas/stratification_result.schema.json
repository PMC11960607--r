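{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tauvisread stratification result",
  "type": "object",
  "required": ["tier", "high_tau", "mcc", "step1", "config_fingerprint"],
  "definitions": {
    "score_set": {
      "type": "object",
      "required": ["multiplier", "threshold_value", "min_cluster_voxels",
                   "scheme", "scores", "max_cluster_voxels"],
      "properties": {
        "multiplier": {"type": "number", "exclusiveMinimum": 0},
        "threshold_value": {"type": "number", "exclusiveMinimum": 0},
        "min_cluster_voxels": {"type": "integer", "minimum": 1},
        "scheme": {"enum": ["step1", "step2"]},
        "scores": {"type": "object",
                   "additionalProperties": {"type": "boolean"}},
        "max_cluster_voxels": {"type": "object",
                               "additionalProperties": {"type": "integer"}}
      }
    }
  },
  "properties": {
    "tier": {"enum": ["tau_ad_negative", "tau_ad_plus",
                      "tau_ad_plusplus"]},
    "high_tau": {"type": "boolean"},
    "mcc": {
      "type": "object",
      "required": ["value", "n_voxels", "method"],
      "properties": {
        "value": {"type": "number", "exclusiveMinimum": 0},
        "n_voxels": {"type": "integer", "minimum": 1},
        "method": {"enum": ["mask3d", "slice2d"]}
      }
    },
    "step1": {"$ref": "#/definitions/score_set"},
    "step2": {"oneOf": [{"$ref": "#/definitions/score_set"},
                        {"type": "null"}]},
    "config_fingerprint": {"type": "string"}
  }
}
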