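{
  "species": [
    {
      "name": "M1",
      "size": 20
    },
    {
      "name": "P1",
      "size": 200
    },
    {
      "name": "M2",
      "size": 20
    },
    {
      "name": "P2",
      "size": 200
    },
    {
      "name": "M3",
      "size": 20
    },
    {
      "name": "P3",
      "size": 200
    }
  ],
  "reactions": [
    {
      "reactants": {},
      "products": {
        "M1": 1
      },
      "kinetics": {
        "kind": "hill",
        "vmax": 2,
        "K": 40,
        "n": 3,
        "regulator": "P3",
        "type": "repressor"
      }
    },
    {
      "reactants": {
        "M1": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.2
      }
    },
    {
      "reactants": {
        "M1": 1
      },
      "products": {
        "M1": 1,
        "P1": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.8
      }
    },
    {
      "reactants": {
        "P1": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.05
      }
    },
    {
      "reactants": {},
      "products": {
        "M2": 1
      },
      "kinetics": {
        "kind": "hill",
        "vmax": 2,
        "K": 40,
        "n": 3,
        "regulator": "P1",
        "type": "repressor"
      }
    },
    {
      "reactants": {
        "M2": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.2
      }
    },
    {
      "reactants": {
        "M2": 1
      },
      "products": {
        "M2": 1,
        "P2": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.8
      }
    },
    {
      "reactants": {
        "P2": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.05
      }
    },
    {
      "reactants": {},
      "products": {
        "M3": 1
      },
      "kinetics": {
        "kind": "hill",
        "vmax": 2,
        "K": 40,
        "n": 3,
        "regulator": "P2",
        "type": "repressor"
      }
    },
    {
      "reactants": {
        "M3": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.2
      }
    },
    {
      "reactants": {
        "M3": 1
      },
      "products": {
        "M3": 1,
        "P3": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.8
      }
    },
    {
      "reactants": {
        "P3": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.05
      }
    }
  ],
  "parameters": [],
  "initial": {
    "kind": "product",
    "dists": [
      {
        "kind": "point",
        "value": 10
      },
      {
        "kind": "point",
        "value": 0
      },
      {
        "kind": "point",
        "value": 0
      },
      {
        "kind": "point",
        "value": 0
      },
      {
        "kind": "point",
        "value": 0
      },
      {
        "kind": "point",
        "value": 0
      }
    ],
    "names": [
      "M1",
      "P1",
      "M2",
      "P2",
      "M3",
      "P3"
    ]
  }
}
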