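# CBA/CaJ mouse auditory profile (normal-hearing strain).
# Audiogram anchors approximate published behavioral thresholds
# (best sensitivity near 16 kHz); Bs(f) is a power-law fit to
# physiological tuning-bandwidth estimates.
# Approximation -- re-digitize from the primary sources for publication use.
species: mouse_cba
range_hz: [2000.0, 80000.0]
threshold:
  frequency_hz: [2000.0, 4000.0, 8000.0, 12000.0, 16000.0, 24000.0, 32000.0, 48000.0, 64000.0, 80000.0]
  level_db: [55.0, 36.0, 20.0, 16.0, 15.0, 18.0, 24.0, 32.0, 42.0, 60.0]
bandwidth:
  a: 0.8017
  b: 0.85
provenance: >-
  Behavioral audiogram and physiological tuning-bandwidth approximations
  for CBA/CaJ mice; power-law fit to literature anchor points.
  Approximation only.
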