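individual_threshold: 1000.0
sequence_threshold: 0.125
cache_budget_bytes: 2.6843546e+08
cache_ttl_seconds: 300.0
http_timeout_seconds: 30.0
ruler_height: 20.0
pixel_width: 1000.0
output_format: svg
styles:
  default:
    glyph: box
    fg_color: '#3366CC'
    bg_color: '#FFFFFF'
    track_height: 60.0
    row_height: 12.0
    min_gap_px: 2.0
    show_labels: no
  transcription:
    glyph: arrow
    fg_color: '#CC4422'
    bg_color: '#FFFFFF'
    track_height: 60.0
    row_height: 12.0
    min_gap_px: 2.0
    show_labels: no
  variation:
    glyph: tick
    fg_color: '#228833'
    bg_color: '#FFFFFF'
    track_height: 30.0
    row_height: 12.0
    min_gap_px: 2.0
    show_labels: no
  repeat_region:
    glyph: box
    fg_color: '#888888'
    bg_color: '#FFFFFF'
    track_height: 30.0
    row_height: 12.0
    min_gap_px: 2.0
    show_labels: no
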