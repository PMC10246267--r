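{
  "schema": "navgate-fixture/1",
  "name": "DIIIAA",
  "description": "DIII S6 double alanine I1284A_I1288A: conductive leaky inactivated state, reduced selectivity",
  "open_pna_pk": 11,
  "leak_pna_pk": 4,
  "leak_na_fraction": 0.19,
  "act_shift_mV": 0,
  "div_shift_mV": 6.5,
  "gate_shift_mV": 14,
  "bind_scale": 1,
  "close_scale": 1,
  "open_prob_scale": 1,
  "n_channels": 200000000,
  "p_abs": 2e-14,
  "cap_nF": 20,
  "clamp_tau_ms": 0.075,
  "targets": {
    "iss_ipeak_60mV": 0.2,
    "immobilized_fraction": 0.6,
    "open_pna_pk": 11,
    "leak_pna_pk": 4
  }
}
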