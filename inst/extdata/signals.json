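{
  "_note": "Ten exogenous input patterns s(t) on [0, 300] min. All share one template: s(t) = baseline + amplitude*(1 - exp(-beta_on*t)) while t <= t_switch, then exponential decay at rate beta_off from the switch value. 'fast' initiation beta_on = 0.5/min (e-fold ~2 min), 'slow' 0.02/min (e-fold 50 min); 'fast' decay beta_off = 0.2/min, 'slow' 0.01/min. Patterns cover every fast/slow initiation x decay combination at two stimulus durations (90 and 210 min) plus two sustained inputs.",
  "patterns": [
    {"id": "S1",  "rise": "fast", "decay": "fast",      "amplitude": 1.0, "baseline": 0.0, "beta_on": 0.5,  "beta_off": 0.2,  "t_switch": 90},
    {"id": "S2",  "rise": "fast", "decay": "slow",      "amplitude": 1.0, "baseline": 0.0, "beta_on": 0.5,  "beta_off": 0.01, "t_switch": 90},
    {"id": "S3",  "rise": "slow", "decay": "fast",      "amplitude": 1.0, "baseline": 0.0, "beta_on": 0.02, "beta_off": 0.2,  "t_switch": 90},
    {"id": "S4",  "rise": "slow", "decay": "slow",      "amplitude": 1.0, "baseline": 0.0, "beta_on": 0.02, "beta_off": 0.01, "t_switch": 90},
    {"id": "S5",  "rise": "fast", "decay": "fast",      "amplitude": 1.0, "baseline": 0.0, "beta_on": 0.5,  "beta_off": 0.2,  "t_switch": 210},
    {"id": "S6",  "rise": "slow", "decay": "fast",      "amplitude": 1.0, "baseline": 0.0, "beta_on": 0.02, "beta_off": 0.2,  "t_switch": 210},
    {"id": "S7",  "rise": "fast", "decay": "slow",      "amplitude": 1.0, "baseline": 0.0, "beta_on": 0.5,  "beta_off": 0.01, "t_switch": 210},
    {"id": "S8",  "rise": "slow", "decay": "slow",      "amplitude": 1.0, "baseline": 0.0, "beta_on": 0.02, "beta_off": 0.01, "t_switch": 210},
    {"id": "S9",  "rise": "fast", "decay": "sustained", "amplitude": 1.0, "baseline": 0.0, "beta_on": 0.5,  "beta_off": 0.0,  "t_switch": 1e6},
    {"id": "S10", "rise": "slow", "decay": "sustained", "amplitude": 1.0, "baseline": 0.0, "beta_on": 0.02, "beta_off": 0.0,  "t_switch": 1e6}
  ]
}
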