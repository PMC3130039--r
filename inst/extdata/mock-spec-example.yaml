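seed: 42
title: Synthetic annotation source
coordinate_system: synthetic-1.0
segments:
  chr1: 2000000.0
  chr2: 1000000.0
classes:
- type_id: gene
  count: 300
  min_len: 500.0
  max_len: 50000.0
  scored: no
  stranded: yes
  grouped_fraction: 0.5
  type_category: transcription
- type_id: exon
  count: 1500
  min_len: 100.0
  max_len: 1000.0
  scored: no
  stranded: yes
  grouped_fraction: 0.8
  type_category: transcription
- type_id: repeat
  count: 2000
  min_len: 100.0
  max_len: 5000.0
  scored: yes
  stranded: no
  grouped_fraction: 0.0
  type_category: repeat_region
- type_id: snv
  count: 1000
  min_len: 1.0
  max_len: 1.0
  scored: yes
  stranded: no
  grouped_fraction: 0.0
  type_category: variation
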