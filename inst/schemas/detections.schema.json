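{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "echoqc per-frame oriented-box detections (conf omitted for ground truth)",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["frame", "detections"],
    "properties": {
      "frame": {"type": "integer", "minimum": 0},
      "detections": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["label", "cx", "cy", "w", "h", "theta"],
          "properties": {
            "label": {"enum": ["LV", "RV", "LA", "RA", "IVS", "MV", "TV"]},
            "cx": {"type": "number"},
            "cy": {"type": "number"},
            "w": {"type": "number", "exclusiveMinimum": 0},
            "h": {"type": "number", "exclusiveMinimum": 0},
            "theta": {"type": "number", "minimum": 0, "exclusiveMaximum": 180},
            "conf": {"type": "number", "minimum": 0, "maximum": 1}
          }
        }
      }
    }
  }
}
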