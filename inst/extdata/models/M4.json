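{
  "id": "M4",
  "name": "Incoherent feedforward loop",
  "_note": "The input signal activates both the output X* (reaction A) and its deactivator Y (reaction FFA); active Y* removes X* through DS, so the output responds transiently even under sustained input. FFR resets the feedforward arm, D is weak basal deactivation.",
  "species": [
    {
      "name": "X",
      "init": 100
    },
    {
      "name": "Xa",
      "init": 0
    },
    {
      "name": "Y",
      "init": 100
    },
    {
      "name": "Ya",
      "init": 0
    }
  ],
  "pools": [
    {
      "members": [
        "X",
        "Xa"
      ],
      "total": 100
    },
    {
      "members": [
        "Y",
        "Ya"
      ],
      "total": 100
    }
  ],
  "output": "Xa",
  "reactions": [
    {
      "label": "A",
      "type": "mm_signal",
      "from": "X",
      "to": "Xa",
      "substrate": "X",
      "k": {
        "name": "k1",
        "value": 6.0
      },
      "km": {
        "name": "km1",
        "value": 30.0
      }
    },
    {
      "label": "D",
      "type": "mass_action",
      "from": "Xa",
      "to": "X",
      "substrate": "Xa",
      "k": {
        "name": "k2a",
        "value": 0.02
      }
    },
    {
      "label": "DS",
      "type": "mm_mod",
      "from": "Xa",
      "to": "X",
      "substrate": "Xa",
      "modifier": "Ya",
      "k": {
        "name": "k2b",
        "value": 0.3
      },
      "km": {
        "name": "km2",
        "value": 30.0
      }
    },
    {
      "label": "FFA",
      "type": "mm_signal",
      "from": "Y",
      "to": "Ya",
      "substrate": "Y",
      "k": {
        "name": "k3",
        "value": 0.3,
        "_note": "signal-driven activation of the deactivator; slower than A so the output peaks before it is quenched"
      },
      "km": {
        "name": "km3",
        "value": 30.0
      }
    },
    {
      "label": "FFR",
      "type": "mass_action",
      "from": "Ya",
      "to": "Y",
      "substrate": "Ya",
      "k": {
        "name": "k4",
        "value": 0.01
      }
    }
  ]
}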