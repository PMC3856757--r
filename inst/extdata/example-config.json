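{
  "pattern": "p1",
  "tau_pct": 30,
  "rho_among": -0.75,
  "dispersal_rate": 0.64,
  "migration": "stepping_stone",
  "order": "move_first",
  "n_generations": 2000,
  "n_success": 5,
  "max_attempts": 60,
  "master_seed": 42
}
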