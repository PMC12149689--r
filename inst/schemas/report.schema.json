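{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "echoqc video QC report",
  "type": "object",
  "required": ["video_id", "video_total", "standard", "cycles", "config_echo"],
  "properties": {
    "video_id": {"type": "string"},
    "video_total": {"type": "integer", "minimum": 0, "maximum": 5},
    "standard": {"type": "boolean"},
    "cycles": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["pattern", "ed_frame", "es_frame", "scores", "total", "reasons"],
        "properties": {
          "pattern": {"enum": ["ED_ES_ED", "ES_ED_ES", null]},
          "ed_frame": {"type": ["integer", "null"], "minimum": 0},
          "es_frame": {"type": ["integer", "null"], "minimum": 0},
          "scores": {
            "type": "object",
            "required": ["gain", "depth", "caa", "structure"],
            "properties": {
              "gain": {"enum": [0, 1]},
              "depth": {"enum": [0, 1]},
              "caa": {"enum": [0, 1]},
              "structure": {"enum": [0, 2]}
            }
          },
          "total": {"type": "integer", "minimum": 0, "maximum": 5},
          "reasons": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "config_echo": {"type": "object"}
  }
}
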