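{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "germvar per-sample report",
  "type": "object",
  "required": ["tool", "version", "sample", "modules"],
  "properties": {
    "tool": {"type": "string"},
    "version": {"type": "string"},
    "sample": {"type": "string"},
    "modules": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["status"],
        "properties": {"status": {"type": "string"}}
      }
    }
  }
}
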