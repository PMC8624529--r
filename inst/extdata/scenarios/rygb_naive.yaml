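scenario: rygb_naive
multiplier: 1.0
base_peff_cm_s: 1.0e-4
segment_ratios:
  jejunum: 1.0
  mid_SI: 0.75
  ileum: 0.5
duodenal_ratio: 1.2
colon_factor: 0.1
settings:
  t_end_h: 96.0
  output_step_h: 0.05
  rtol: 1.0e-10
  atol: 1.0e-10
  colonic_asf: 0.1
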