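{
  "c_tot": 0.2,
  "coupling_mode": "uncoupled",
  "n_inputs": 2,
  "s_c": 1,
  "output_node": "node3",
  "kinetics": {
    "gamma1": 1000,
    "gamma2": 10,
    "delta": 1
  },
  "nodes": [
    {
      "id": "node1",
      "layer": 1,
      "bias": [
        {
          "w": 1.2,
          "sign": "-"
        }
      ],
      "weights": {
        "x1": {
          "w": 1,
          "sign": "+"
        },
        "x2": {
          "w": 1,
          "sign": "+"
        }
      }
    },
    {
      "id": "node2",
      "layer": 1,
      "bias": [
        {
          "w": 0.7,
          "sign": "+"
        }
      ],
      "weights": {
        "x1": {
          "w": 1,
          "sign": "-"
        },
        "x2": {
          "w": 1,
          "sign": "-"
        }
      }
    },
    {
      "id": "node3",
      "layer": 2,
      "bias": [
        {
          "w": 0.15,
          "sign": "-"
        }
      ],
      "weights": {
        "node1": {
          "w": 4,
          "sign": "+"
        },
        "node2": {
          "w": 4,
          "sign": "+"
        }
      }
    }
  ]
}
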