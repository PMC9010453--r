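# C57BL/6J mouse auditory profile. The strain develops progressive
# high-frequency hearing loss from ~7 weeks of age; anchors reflect
# young-adult thresholds that are elevated relative to CBA/CaJ,
# especially above 16 kHz. Bandwidth function shared with mouse_cba.
# Approximation -- re-digitize from the primary sources for publication use.
species: mouse_c57bl6j
range_hz: [2000.0, 60000.0]
threshold:
  frequency_hz: [2000.0, 4000.0, 8000.0, 12000.0, 16000.0, 24000.0, 32000.0, 48000.0, 60000.0]
  level_db: [60.0, 45.0, 30.0, 27.0, 25.0, 32.0, 45.0, 65.0, 80.0]
bandwidth:
  a: 0.8017
  b: 0.85
provenance: >-
  Behavioral audiogram approximations for young-adult C57BL/6J mice with
  early-onset high-frequency loss; bandwidth power law shared with CBA/CaJ.
  Approximation only.
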