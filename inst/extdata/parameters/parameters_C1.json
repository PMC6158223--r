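{
  "level": "C1",
  "description": "As level C but chemical transmission is through continuously transmitting graded (analogue) synapses; gap junctions unchanged.",
  "neuron_params": {
    "model": "conductance",
    "C_m": 10.0,
    "g_leak": 0.3,
    "E_leak": -60.0,
    "ca_rho": 0.002,
    "ca_tau": 60.0,
    "spike_detect_threshold": -20.0,
    "channels": [
      {
        "name": "k_fast",
        "gbar": 8.0,
        "E_rev": -80.0,
        "is_calcium_carrier": false,
        "activation": {
          "V_half": -25.0,
          "slope_k": 9.0,
          "tau": 3.0,
          "exponent": 4
        }
      },
      {
        "name": "ca",
        "gbar": 3.0,
        "E_rev": 60.0,
        "is_calcium_carrier": true,
        "activation": {
          "V_half": -25.0,
          "slope_k": 5.0,
          "tau": 2.0,
          "exponent": 2
        },
        "inactivation": {
          "V_half": -50.0,
          "slope_k": -8.0,
          "tau": 40.0,
          "exponent": 1
        }
      }
    ]
  },
  "muscle_params": {
    "model": "conductance",
    "C_m": 20.0,
    "g_leak": 0.3,
    "E_leak": -60.0,
    "ca_rho": 0.002,
    "ca_tau": 60.0,
    "spike_detect_threshold": -20.0,
    "channels": [
      {
        "name": "k_fast",
        "gbar": 10.0,
        "E_rev": -80.0,
        "is_calcium_carrier": false,
        "activation": {
          "V_half": -25.0,
          "slope_k": 9.0,
          "tau": 2.0,
          "exponent": 4
        },
        "inactivation": {
          "V_half": -45.0,
          "slope_k": -6.0,
          "tau": 60.0,
          "exponent": 1
        }
      },
      {
        "name": "k_slow",
        "gbar": 4.0,
        "E_rev": -80.0,
        "is_calcium_carrier": false,
        "activation": {
          "V_half": -10.0,
          "slope_k": 4.0,
          "tau": 30.0,
          "exponent": 1
        }
      },
      {
        "name": "ca",
        "gbar": 4.0,
        "E_rev": 60.0,
        "is_calcium_carrier": true,
        "activation": {
          "V_half": -25.0,
          "slope_k": 5.0,
          "tau": 2.0,
          "exponent": 2
        },
        "inactivation": {
          "V_half": -50.0,
          "slope_k": -8.0,
          "tau": 50.0,
          "exponent": 1
        }
      }
    ]
  },
  "exc_syn": {
    "kind": "graded",
    "E_syn": 0.0,
    "V_th_pre": -35.0,
    "delta": 3.0,
    "tau_s": 30.0
  },
  "inh_syn": {
    "kind": "graded",
    "E_syn": -70.0,
    "V_th_pre": -35.0,
    "delta": 3.0,
    "tau_s": 30.0
  },
  "gap": {
    "as_spike_synapse": false
  },
  "baseline_chem": 0.01,
  "baseline_gap": 0.01
}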