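{
  "species": [
    {
      "name": "S1",
      "size": 10
    },
    {
      "name": "S2",
      "size": 10
    },
    {
      "name": "S3",
      "size": 10
    }
  ],
  "reactions": [
    {
      "reactants": {},
      "products": {
        "S1": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 2.4
      }
    },
    {
      "reactants": {
        "S1": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.6
      }
    },
    {
      "reactants": {
        "S1": 1
      },
      "products": {
        "S2": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 1
      }
    },
    {
      "reactants": {},
      "products": {
        "S2": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.9
      }
    },
    {
      "reactants": {
        "S2": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.6
      }
    },
    {
      "reactants": {
        "S2": 1
      },
      "products": {
        "S3": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 1
      }
    },
    {
      "reactants": {},
      "products": {
        "S3": 1
      },
      "kinetics": {
        "kind": "mass_action",
        "rate": 0.9
      }
    },
    {
      "reactants": {
        "S3": 1
      },
      "products": {},
      "kinetics": {
        "kind": "mass_action",
        "rate": 1.6
      }
    }
  ],
  "parameters": [],
  "initial": {
    "kind": "product",
    "dists": [
      {
        "kind": "poisson",
        "mean": 0.5
      },
      {
        "kind": "poisson",
        "mean": 0.5
      },
      {
        "kind": "poisson",
        "mean": 0.5
      }
    ],
    "names": [
      "S1",
      "S2",
      "S3"
    ]
  }
}
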