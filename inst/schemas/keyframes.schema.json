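{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "echoqc keyframe annotation (0-based frame indices)",
  "type": "object",
  "required": ["video_id", "n_frames", "keyframes"],
  "properties": {
    "video_id": {"type": "string"},
    "n_frames": {"type": "integer", "minimum": 1},
    "keyframes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["frame", "phase"],
        "properties": {
          "frame": {"type": "integer", "minimum": 0},
          "phase": {"enum": ["ED", "ES"]}
        }
      }
    }
  }
}
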