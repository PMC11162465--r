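{
  "species": [
    {
      "name": "G0",
      "size": 2
    },
    {
      "name": "G1",
      "size": 2
    },
    {
      "name": "G2",
      "size": 2
    },
    {
      "name": "mRNA",
      "size": 151
    }
  ],
  "reactions": [
    {
      "reactants": {
        "G0": 1
      },
      "products": {
        "G1": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": {
          "param": "k1"
        }
      }
    },
    {
      "reactants": {
        "G1": 1
      },
      "products": {
        "G0": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": {
          "param": "k2"
        }
      }
    },
    {
      "reactants": {
        "G1": 1
      },
      "products": {
        "G2": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": {
          "param": "k3"
        }
      }
    },
    {
      "reactants": {
        "G2": 1
      },
      "products": {
        "G1": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": {
          "param": "k4"
        }
      }
    },
    {
      "reactants": {},
      "products": {
        "mRNA": 1
      },
      "kinetics": {
        "kind": "lin_comb",
        "coef": [
          {
            "param": "kp1"
          },
          {
            "param": "kp1"
          },
          {
            "param": "kp2"
          }
        ],
        "species": [
          "G1",
          "G2",
          "G2"
        ]
      }
    },
    {
      "reactants": {
        "mRNA": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 1
      }
    }
  ],
  "parameters": [
    {
      "name": "k1",
      "grid": [0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5, 0.55, 0.6, 0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95, 1],
      "prior": [0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476]
    },
    {
      "name": "k2",
      "grid": [0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5, 0.55, 0.6, 0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95, 1],
      "prior": [0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476]
    },
    {
      "name": "k3",
      "grid": [0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5, 0.55, 0.6, 0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95, 1],
      "prior": [0.5, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025]
    },
    {
      "name": "k4",
      "grid": [0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9, 2],
      "prior": [0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476, 0.0476190476190476]
    },
    {
      "name": "kp1",
      "grid": [0, 8, 16, 24, 32, 40, 48, 56, 64, 72, 80],
      "prior": [0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909]
    },
    {
      "name": "kp2",
      "grid": [20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120],
      "prior": [0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909, 0.0909090909090909]
    }
  ],
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
      "G0",
      "G1",
      "G2",
      "mRNA"
    ]
  }
}
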