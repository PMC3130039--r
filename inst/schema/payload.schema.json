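{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "dastrack payload envelope",
  "description": "Versioned JSON interchange for feature/bin payloads reduced to a zoom tier. Coordinates are 1-based inclusive.",
  "type": "object",
  "required": ["format", "format_version", "segment", "tier", "payload_kind", "payload"],
  "properties": {
    "format": { "const": "dastrack-payload" },
    "format_version": { "type": "string", "description": "Readers reject versions they do not know; current: 1.0" },
    "segment": {
      "type": "object",
      "required": ["segment_id", "start", "stop"],
      "properties": {
        "segment_id": { "type": "string" },
        "start": { "type": "number", "minimum": 1 },
        "stop": { "type": "number" }
      }
    },
    "tier": {
      "type": "object",
      "required": ["kind", "bases_per_pixel"],
      "properties": {
        "kind": { "enum": ["sequence", "individual", "summary"] },
        "bases_per_pixel": { "type": "number", "exclusiveMinimum": 0 },
        "bin_width": { "type": "number", "minimum": 1, "description": "present iff kind is summary" }
      }
    },
    "payload_kind": { "enum": ["features", "bins"] },
    "payload": {
      "type": "array",
      "items": {
        "oneOf": [
          {
            "type": "object",
            "required": ["feature_id", "type_id", "start", "stop", "orientation", "notes"],
            "properties": {
              "feature_id": { "type": "string" },
              "label": { "type": "string" },
              "type_id": { "type": "string" },
              "type_category": { "type": "string" },
              "method": { "type": "string" },
              "start": { "type": "number", "minimum": 1 },
              "stop": { "type": "number", "minimum": 1 },
              "score": { "type": "number" },
              "orientation": { "enum": ["forward", "reverse", "unstranded"] },
              "phase": { "enum": [0, 1, 2] },
              "group_id": { "type": "string" },
              "link": { "type": "string" },
              "notes": { "type": "array", "items": { "type": "string" } }
            }
          },
          {
            "type": "object",
            "required": ["bin_start", "bin_stop", "count", "coverage_fraction"],
            "properties": {
              "bin_start": { "type": "number", "minimum": 1 },
              "bin_stop": { "type": "number", "minimum": 1 },
              "count": { "type": "integer", "minimum": 0 },
              "coverage_fraction": { "type": "number", "minimum": 0, "maximum": 1 },
              "max_score": { "type": "number" }
            }
          }
        ]
      }
    }
  }
}
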