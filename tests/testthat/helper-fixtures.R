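# Small in-code fixtures shared across the suite.

# wormwiring-dialect CSV lines for a hand-traceable 4-cell circuit.
ww_fixture_csv <- function() {
  c("Origin,Target,Type,Number of Connections,Neurotransmitter",
    "AVBL,DB1,GapJunction,2,",
    "DB1,MDL08,Send,5,Acetylcholine",
    "DD1,MDL08,Send,3,GABA")
}

# A LIF parameter block for direct dynamics tests.
lif_fixture <- function(C_m = 10, g_leak = 0.5, E_leak = -60,
                        V_thresh = -40, V_reset = -60, t_refract = 2) {
  list(C_m = C_m, g_leak = g_leak, E_leak = E_leak,
       V_thresh = V_thresh, V_reset = V_reset, t_refract = t_refract)
}

# A one-neuron network with chosen LIF constants, for closed-form checks.
single_lif_network <- function(..., level = "A") {
  p <- unclass(default_parameters(level))
  p$neuron_params <- utils::modifyList(p$neuron_params, list(...))
  cx <- connectome(cells = tibble::tibble(
    name = "N1", cell_class = "interneuron", neurotransmitter = "UNKNOWN",
    x = 0, y = 0, z = 0))
  build_network(cx, validate_parameter_set(p))
}

# Two passive cells (no leak, no threshold) coupled by one gap junction,
# starting from different potentials (via their leak reversals).
gap_pair_network <- function(g_gap = 1, E_a = -70, E_b = -50, C_m = 10) {
  p <- unclass(default_parameters("B"))
  p$neuron_params <- utils::modifyList(
    p$neuron_params, list(g_leak = 0, E_leak = E_a, V_thresh = 1e6, C_m = C_m))
  p$muscle_params <- utils::modifyList(
    p$muscle_params, list(g_leak = 0, E_leak = E_b, V_thresh = 1e6, C_m = C_m))
  p$baseline_gap <- g_gap
  cells <- tibble::tibble(
    name = c("A", "B"), cell_class = c("interneuron", "muscle"),
    neurotransmitter = "UNKNOWN", x = c(0, 1), y = 0, z = 0)
  cx <- connectome(cells = cells,
                   electrical = tibble::tibble(cell_a = "A", cell_b = "B",
                                               n_contacts = 1L))
  build_network(cx, validate_parameter_set(p))
}

# Synthetic travelling-wave calcium traces: unit-amplitude sinusoids with a
# fixed per-muscle delay. Returns a wide data frame (time + one column per
# muscle named within `quadrant`).
sinusoid_traces <- function(n_muscles = 10, delay = 20, period = 1000,
                            t_max = 3000, dt = 5, quadrant = "MDL",
                            phase_shift = 0) {
  tt <- seq(0, t_max, by = dt)
  out <- tibble::tibble(time = tt)
  for (i in seq_len(n_muscles)) {
    out[[sprintf("%s%02d", quadrant, i)]] <-
      sin(2 * pi * (tt - (i - 1) * delay - phase_shift) / period)
  }
  out
}
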