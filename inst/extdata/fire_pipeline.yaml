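# Analysis settings for the global active-fire chronnet pipeline.
# Records: MCD14ML-style detections; only confidence strictly above 75% is
# kept, all type codes retained so static outlier sources stay detectable.
min_confidence: 75
keep_types: all
h: 1
tau: 2
outlier_fraction: 0.01
strongest_link_fraction: 0.20
community_method: label_propagation
restarts: 10
# Used only when no external (e.g. hexagonal DGGS) cell assignment is given.
fallback_grid:
  nx: 360
  ny: 180
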