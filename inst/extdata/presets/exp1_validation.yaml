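# Model-validation run: constant 1 bar, 0.8 M draw, 6 h batch
# (the 0.5 M / 2.0 M and 2-3 bar variants are obtained by editing
# draw_molarity_M / P_bar).
scenario: pro
pro:
  feed_volume_mL: 600
  feed_substrate_mg_L: 193
  draw_molarity_M: 0.8
  draw_volume_mL: 600
  pressure_policy: constant
  P_bar: 1
  flux_stop_LMH: 0.001
  t_max_h: 6
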