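{
  "schema": "navgate-fixture/1",
  "name": "I1288A",
  "description": "DIII S6 single alanine (bottom ring): WT-like currents, right-shifted activation and availability",
  "open_pna_pk": 11,
  "leak_pna_pk": null,
  "leak_na_fraction": 0,
  "act_shift_mV": 9.6,
  "div_shift_mV": 10,
  "gate_shift_mV": 0,
  "bind_scale": 1,
  "close_scale": 1,
  "open_prob_scale": 1,
  "n_channels": 200000000,
  "p_abs": 2e-14,
  "cap_nF": 20,
  "clamp_tau_ms": 0.075,
  "targets": []
}
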