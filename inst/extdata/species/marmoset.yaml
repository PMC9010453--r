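# Common marmoset (Callithrix jacchus) auditory profile.
# Audiogram anchors approximate the published behavioral audiogram
# (best sensitivity ~10.6 dB SPL near 8 kHz); the tuning bandwidth Bs(f)
# is a log-log power-law fit to behavioral critical-band estimates.
# Approximation -- re-digitize from the primary sources for publication use.
species: marmoset
range_hz: [125.0, 36000.0]
threshold:
  frequency_hz: [125.0, 250.0, 500.0, 1000.0, 2000.0, 4000.0, 7000.0, 8000.0, 10000.0, 16000.0, 24000.0, 28000.0, 33000.0, 36000.0]
  level_db: [52.0, 38.0, 30.0, 26.0, 22.0, 16.0, 11.0, 10.6, 12.0, 17.0, 22.0, 28.0, 38.0, 48.0]
bandwidth:
  a: 0.6194
  b: 0.774
provenance: >-
  Behavioral audiogram and critical-band approximations for Callithrix
  jacchus; power-law fit to literature anchor points. Approximation only.
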