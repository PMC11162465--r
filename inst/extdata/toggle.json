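{
  "species": [
    {
      "name": "Ga",
      "size": 2
    },
    {
      "name": "Gb",
      "size": 2
    },
    {
      "name": "Pa",
      "size": 200
    },
    {
      "name": "Pb",
      "size": 200
    }
  ],
  "reactions": [
    {
      "reactants": {},
      "products": {
        "Ga": 1
      },
      "kinetics": {
        "kind": "lin_comb",
        "coef": [
          0.05,
          -0.05
        ],
        "species": [
          null,
          "Ga"
        ]
      }
    },
    {
      "reactants": {
        "Ga": 1,
        "Pb": 1
      },
      "products": {
        "Pb": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.005
      }
    },
    {
      "reactants": {
        "Ga": 1
      },
      "products": {
        "Ga": 1,
        "Pa": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 8
      }
    },
    {
      "reactants": {
        "Pa": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.08
      }
    },
    {
      "reactants": {},
      "products": {
        "Gb": 1
      },
      "kinetics": {
        "kind": "lin_comb",
        "coef": [
          0.05,
          -0.05
        ],
        "species": [
          null,
          "Gb"
        ]
      }
    },
    {
      "reactants": {
        "Gb": 1,
        "Pa": 1
      },
      "products": {
        "Pa": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.005
      }
    },
    {
      "reactants": {
        "Gb": 1
      },
      "products": {
        "Gb": 1,
        "Pb": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 8
      }
    },
    {
      "reactants": {
        "Pb": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.08
      }
    }
  ],
  "parameters": [],
  "initial": {
    "kind": "product",
    "dists": [
      {
        "kind": "point",
        "value": 1
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
      "Ga",
      "Gb",
      "Pa",
      "Pb"
    ]
  }
}
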