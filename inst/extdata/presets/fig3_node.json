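{
  "c_tot": 0.5,
  "coupling_mode": "uncoupled",
  "n_inputs": 2,
  "s_c": 1,
  "output_node": "node1",
  "kinetics": {
    "gamma1": 100,
    "gamma2": 10,
    "delta": 1
  },
  "nodes": [
    {
      "id": "node1",
      "layer": 1,
      "bias": [],
      "weights": {
        "x1": {
          "w": 1,
          "sign": "+"
        },
        "x2": {
          "w": 1,
          "sign": "-"
        }
      }
    }
  ]
}
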