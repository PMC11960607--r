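{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tauvisread agreement report",
  "type": "object",
  "required": ["per_reader", "pooled", "medians", "fleiss",
               "success_ppa_npa", "success_fleiss"],
  "definitions": {
    "proportion": {
      "type": "object",
      "required": ["numerator", "denominator", "point_pct",
                   "ci_low_pct", "ci_high_pct", "level"],
      "properties": {
        "numerator": {"type": "integer", "minimum": 0},
        "denominator": {"type": "integer", "minimum": 1},
        "point_pct": {"type": "number", "minimum": 0, "maximum": 100},
        "ci_low_pct": {"type": "number", "minimum": 0, "maximum": 100},
        "ci_high_pct": {"type": "number", "minimum": 0, "maximum": 100},
        "level": {"type": "number", "exclusiveMinimum": 0,
                  "exclusiveMaximum": 1}
      }
    },
    "kappa": {
      "type": "object",
      "required": ["statistic", "se", "ci_low", "ci_high", "method"],
      "properties": {
        "statistic": {"type": "number", "minimum": -1, "maximum": 1},
        "se": {"type": "number", "minimum": 0},
        "ci_low": {"type": "number"},
        "ci_high": {"type": "number", "maximum": 1},
        "method": {"enum": ["fleiss", "cohen"]}
      }
    },
    "reader_row": {
      "type": "object",
      "required": ["reader", "tp", "fp", "tn", "fn", "ppa", "npa",
                   "overall"],
      "properties": {
        "tp": {"type": "integer"}, "fp": {"type": "integer"},
        "tn": {"type": "integer"}, "fn": {"type": "integer"},
        "ppa": {"$ref": "#/definitions/proportion"},
        "npa": {"$ref": "#/definitions/proportion"},
        "overall": {"$ref": "#/definitions/proportion"}
      }
    }
  },
  "properties": {
    "per_reader": {
      "type": "object",
      "additionalProperties": {"$ref": "#/definitions/reader_row"}
    },
    "pooled": {"$ref": "#/definitions/reader_row"},
    "medians": {
      "type": "object",
      "required": ["ppa_pct", "npa_pct", "overall_pct"]
    },
    "fleiss": {"$ref": "#/definitions/kappa"},
    "success_ppa_npa": {"type": "boolean"},
    "success_fleiss": {"type": "boolean"}
  }
}
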