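# Example pipeline configuration: only keys that differ from io_config()
# defaults need to appear here.
max_gap_min: 5
baseline_policy: most_recent_7d
missing_policy: complete_case
vitals:
  map_parameter: art_mbp
  map_min: 10
  map_max: 200
labs:
  unit: mg/dl
operations:
  dialect: columns
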