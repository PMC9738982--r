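{
  "name": "CA",
  "wavelength_window": [330, 860],
  "concentration_range": [5e+05, 4e+06],
  "concentration_floor": 10000,
  "components": [
    {
      "amplitude": {"family": "log_linear", "params": [-218.6, 41.1]},
      "center": {"family": "log_linear", "params": [-7884, 1130]},
      "width": {"family": "constant", "params": [2036]}
    },
    {
      "amplitude": {"family": "log_linear", "params": [-182, 33.36]},
      "center": {"family": "constant", "params": [562.3]},
      "width": {"family": "constant", "params": [479.5]}
    }
  ]
}
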