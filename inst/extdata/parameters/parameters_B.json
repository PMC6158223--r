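{
  "level": "B",
  "description": "Leaky integrate-and-fire cells with a low-pass activity variable as a firing-rate proxy; true electrical gap junctions.",
  "neuron_params": {
    "model": "lif",
    "C_m": 10.0, "g_leak": 0.5, "E_leak": -60.0,
    "V_thresh": -40.0, "V_reset": -60.0, "t_refract": 2.0
  },
  "muscle_params": {
    "model": "lif",
    "C_m": 20.0, "g_leak": 0.5, "E_leak": -60.0,
    "V_thresh": -40.0, "V_reset": -60.0, "t_refract": 2.0
  },
  "activity": { "tau_activity": 200.0, "increment_per_spike": 0.1 },
  "exc_syn": { "kind": "spike", "E_syn": 0.0, "tau_decay": 10.0 },
  "inh_syn": { "kind": "spike", "E_syn": -70.0, "tau_decay": 10.0 },
  "gap": { "as_spike_synapse": false },
  "baseline_chem": 0.01,
  "baseline_gap": 0.01
}
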