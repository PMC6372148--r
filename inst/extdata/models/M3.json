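{
  "id": "M3",
  "name": "Negative feedback loop",
  "_note": "The output X* activates its own deactivator Y (reaction FBA); active Y* then removes X* through the signal-shaping deactivation DS, producing partial adaptation. D is a weak basal deactivation, FBR resets the feedback arm.",
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
        "value": 0.02,
        "_note": "basal deactivation, slow relative to DS"
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
        "value": 0.3,
        "_note": "catalytic deactivation per unit active Y*, 1/(conc min)"
      },
      "km": {
        "name": "km2",
        "value": 30.0
      }
    },
    {
      "label": "FBA",
      "type": "mm_mod",
      "from": "Y",
      "to": "Ya",
      "substrate": "Y",
      "modifier": "Xa",
      "k": {
        "name": "k3",
        "value": 0.02,
        "_note": "feedback activation of the deactivator per unit X*"
      },
      "km": {
        "name": "km3",
        "value": 30.0
      }
    },
    {
      "label": "FBR",
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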