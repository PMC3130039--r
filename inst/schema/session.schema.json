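{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "dastrack session file",
  "description": "Flat-text snapshot of the application state: viewers with viewports, tracks and styles, link groups, and registered sources. Sessions store source URLs, never data.",
  "type": "object",
  "required": ["format", "format_version", "viewers", "registered_sources"],
  "properties": {
    "format": { "const": "dastrack-session" },
    "format_version": { "type": "string", "description": "Readers reject versions they do not know; current: 1.0" },
    "viewers": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["viewport", "tracks", "link_role"],
        "properties": {
          "viewport": {
            "type": "object",
            "required": ["segment_id", "start", "stop", "pixel_width"],
            "properties": {
              "segment_id": { "type": "string" },
              "start": { "type": "number", "minimum": 1 },
              "stop": { "type": "number", "minimum": 1 },
              "pixel_width": { "type": "number", "minimum": 1 }
            }
          },
          "tracks": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["source_url", "label", "style"],
              "properties": {
                "source_url": { "type": "string" },
                "label": { "type": "string" },
                "style": {
                  "type": "object",
                  "required": ["glyph", "fg_color", "bg_color", "track_height",
                               "row_height", "min_gap_px", "show_labels"],
                  "properties": {
                    "glyph": { "enum": ["box", "line", "arrow", "tick", "histogram"] },
                    "fg_color": { "type": "string", "pattern": "^#[0-9A-F]{6}$" },
                    "bg_color": { "type": "string", "pattern": "^#[0-9A-F]{6}$" },
                    "track_height": { "type": "number", "minimum": 1 },
                    "row_height": { "type": "number", "minimum": 1 },
                    "min_gap_px": { "type": "number", "minimum": 0 },
                    "show_labels": { "type": "boolean" }
                  }
                }
              }
            }
          },
          "link_group": { "type": "string", "description": "required when link_role is not independent" },
          "link_role": { "enum": ["independent", "same_region_other_zoom", "adjacent_next", "adjacent_previous"] }
        }
      }
    },
    "registered_sources": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["base_url", "title", "capabilities"],
        "properties": {
          "base_url": { "type": "string" },
          "title": { "type": "string" },
          "capabilities": {
            "type": "array",
            "items": { "enum": ["sources", "entry_points", "sequence", "features", "types", "stylesheet"] }
          },
          "coordinate_system": { "type": "string" }
        }
      }
    }
  }
}
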