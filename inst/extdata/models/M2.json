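{
  "id": "M2",
  "name": "Cycle reaction",
  "_note": "Three-state cycle: activation X -> X*, deactivation into a refractory state X* -> Xr, and a saturable recycling reaction Xr -> X that closes the cycle and delays recovery of the available pool.",
  "species": [
    {"name": "X",  "init": 100},
    {"name": "Xa", "init": 0},
    {"name": "Xr", "init": 0}
  ],
  "pools": [
    {"members": ["X", "Xa", "Xr"], "total": 100}
  ],
  "output": "Xa",
  "reactions": [
    {
      "label": "A", "type": "mm_signal",
      "from": "X", "to": "Xa", "substrate": "X",
      "k":  {"name": "k1",  "value": 6.0},
      "km": {"name": "km1", "value": 30.0}
    },
    {
      "label": "D", "type": "mass_action",
      "from": "Xa", "to": "Xr", "substrate": "Xa",
      "k": {"name": "k2a", "value": 0.08}
    },
    {
      "label": "R", "type": "mm",
      "from": "Xr", "to": "X", "substrate": "Xr",
      "k":  {"name": "k3",  "value": 4.0, "_note": "maximal recycling rate, conc/min"},
      "km": {"name": "km3", "value": 30.0}
    }
  ]
}
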