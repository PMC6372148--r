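{
  "id": "M1",
  "name": "Reversible reaction",
  "_note": "Single activation/deactivation cycle: the input signal activates X through a Michaelis-Menten step, X* relaxes back by first-order deactivation. Pool size 100 gives coefficient-of-variation noise of roughly 10% in the Langevin ensemble; rate values give relaxation times of tens of minutes on the 300-min observation window.",
  "species": [
    {"name": "X",  "init": 100},
    {"name": "Xa", "init": 0}
  ],
  "pools": [
    {"members": ["X", "Xa"], "total": 100}
  ],
  "output": "Xa",
  "reactions": [
    {
      "label": "A", "type": "mm_signal",
      "from": "X", "to": "Xa", "substrate": "X",
      "k":  {"name": "k1",  "value": 6.0,  "_note": "maximal activation rate per unit signal, conc/min"},
      "km": {"name": "km1", "value": 30.0, "_note": "half-saturation of the inactive pool, conc"}
    },
    {
      "label": "D", "type": "mass_action",
      "from": "Xa", "to": "X", "substrate": "Xa",
      "k": {"name": "k2a", "value": 0.05, "_note": "first-order deactivation, 1/min (~20 min relaxation)"}
    }
  ]
}
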