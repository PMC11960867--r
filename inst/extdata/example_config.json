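{
  "model": {
    "discount_rate_annual": 0.0,
    "nabpac_admin_per_cycle": 2,
    "monitor_every_n_cycles": 3
  },
  "costs": {
    "cost_toripalimab_cycle": 4446.02
  },
  "psa": {
    "n_iter": 500
  }
}
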