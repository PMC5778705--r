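# Schema example for CDL equation presets: CDL = slope * A + intercept (mm).
# The coefficients below are SYNTHETIC placeholders for illustrating the file
# format only. Transcribe real slope/intercept values from the published
# source you intend to use (e.g. the Alexiades or Koch relations) and cite it
# in `source` before using the estimates clinically.
- name: synthetic_lateral_wall
  slope: 4.2
  intercept: -4.0
  site: lateral_wall
  source: "synthetic example coefficients (placeholder, not published values)"
- name: synthetic_organ_of_corti
  slope: 3.9
  intercept: -3.5
  site: organ_of_corti
  source: "synthetic example coefficients (placeholder, not published values)"
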