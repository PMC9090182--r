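{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "muscnet evaluation result",
  "type": "object",
  "required": ["config", "counts", "metrics", "predictions", "truth",
               "scores", "perFoldSelected"],
  "properties": {
    "config": {"type": "object"},
    "counts": {
      "type": "object",
      "required": ["TP", "FN", "TN", "FP"],
      "properties": {
        "TP": {"type": "integer", "minimum": 0},
        "FN": {"type": "integer", "minimum": 0},
        "TN": {"type": "integer", "minimum": 0},
        "FP": {"type": "integer", "minimum": 0}
      }
    },
    "metrics": {
      "type": "object",
      "required": ["Acc", "Sn", "Sp"],
      "properties": {
        "Acc": {"type": "number", "minimum": 0, "maximum": 1},
        "Sn": {"type": "number", "minimum": 0, "maximum": 1},
        "Sp": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "predictions": {"type": "array", "items": {"enum": [0, 1]}},
    "truth": {"type": "array", "items": {"enum": [0, 1]}},
    "scores": {"type": "array", "items": {"type": "number"}},
    "perFoldSelected": {"type": "array"},
    "alphaTable": {"type": "array"},
    "provenance": {"type": "object"}
  }
}
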