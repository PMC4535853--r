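# MEC external voltage varied 0.5-1.1 V on the feasibility PRO effluents.
scenario: sweep
pro:
  feed_volume_mL: 600
  feed_substrate_mg_L: 193
  draw_molarity_M: 0.8
  draw_volume_mL: 600
  pressure_policy: half_delta_pi
  flux_stop_LMH: 0.5
sweep:
  variable: voltage
  grid: [0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.1]
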