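# System feasibility: PRO at the maximum-power pressure schedule feeding the
# MEC at 0.8 V; MEC runs on the harvested PRO energy.
scenario: system
pro:
  feed_volume_mL: 600
  feed_substrate_mg_L: 193
  draw_molarity_M: 0.8
  draw_volume_mL: 600
  pressure_policy: half_delta_pi
  flux_stop_LMH: 0.5
mec:
  voltage_V: 0.8
  anolyte: {volume_mL: 115, substrate_mg_L: 1007, conductivity_mS_cm: 18.3}
  catholyte: {volume_mL: 1085, molarity_M: 0.46, pH: 11}
coupling:
  use_pro_energy_budget: true
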