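{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mtlrisk experiment results",
  "type": "object",
  "required": ["results", "manifest"],
  "properties": {
    "results": {
      "type": "object",
      "description": "One entry per test set (always 'test'; extra held-out sets by name)",
      "additionalProperties": {
        "type": "object",
        "required": ["Ps", "Pm", "Rs", "Rm", "F1s", "F1m",
                     "ACCs", "ACCm", "AUCs", "AUCm"],
        "properties": {
          "Ps":   {"type": "number", "minimum": 0, "maximum": 1},
          "Pm":   {"type": "number", "minimum": 0, "maximum": 1},
          "Rs":   {"type": "number", "minimum": 0, "maximum": 1},
          "Rm":   {"type": "number", "minimum": 0, "maximum": 1},
          "F1s":  {"type": "number", "minimum": 0, "maximum": 1},
          "F1m":  {"type": "number", "minimum": 0, "maximum": 1},
          "ACCs": {"type": "number", "minimum": 0, "maximum": 1},
          "ACCm": {"type": "number", "minimum": 0, "maximum": 1},
          "AUCs": {"type": "number", "minimum": 0, "maximum": 1},
          "AUCm": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "manifest": {
      "type": "object",
      "required": ["seed", "task", "n_train_pairs", "n_test_pairs",
                   "vocab_size", "max_len"],
      "properties": {
        "seed": {"type": "integer"},
        "task": {"type": "string", "enum": ["flagged", "urgent"]},
        "n_train_pairs": {"type": "integer"},
        "n_test_pairs": {"type": "integer"},
        "vocab_size": {"type": "integer"},
        "max_len": {"type": "integer"},
        "n_splits": {"type": "integer"}
      }
    }
  }
}
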