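{
  "shunt_conductance": 2e-11,
  "offset": -1.12,
  "log_kd": -9,
  "log_k_vehicle_water": 0,
  "vehicle": "water"
}
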