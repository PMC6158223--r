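#' Single forward-Euler step of a leaky integrate-and-fire cell
#'
#' The membrane follows `C_m dV/dt = -g_leak (V - E_leak) + I_total` with
#' threshold-and-reset spiking: when the updated voltage reaches `V_thresh`
#' the cell emits a spike, the voltage is reset to `V_reset`, and the cell is
#' held at reset for the refractory period. All arguments are vectorised over
#' cells.
#'
#' @param V Membrane potential, mV.
#' @param I_total Total input current into the cell, pA (depolarising positive).
#' @param p List with `C_m` (pF), `g_leak` (nS), `E_leak`, `V_thresh`,
#'   `V_reset` (mV) and `t_refract` (ms).
#' @param dt Time step, ms (> 0).
#' @param refract_until Absolute time until which the cell is refractory, ms.
#' @param t Time at the start of the step, ms. A spike detected during the
#'   step is an event at `t + dt`, and the refractory period runs from the
#'   event time.
#' @return List with `V` (updated potential), `spiked` (logical) and
#'   `refract_until`.
#' @export
lif_step <- function(V, I_total, p, dt, refract_until = -Inf, t = 0) {
  if (dt <= 0) stop("dt must be > 0")
  in_refract <- t < refract_until
  V_new <- V + dt * (-p$g_leak * (V - p$E_leak) + I_total) / p$C_m
  V_new[in_refract] <- p$V_reset
  spiked <- !in_refract & V_new >= p$V_thresh
  V_new[spiked] <- p$V_reset
  refract_until[spiked] <- t + dt + p$t_refract
  list(V = V_new, spiked = spiked, refract_until = refract_until)
}

#' Steady state and time constant of a Hodgkin-Huxley gate
#'
#' Boltzmann steady state `x_inf = 1 / (1 + exp((V_half - V) / slope_k))`
#' with a voltage-independent time constant. A negative `slope_k` gives a
#' falling curve, as used for inactivation gates.
#'
#' @param V Membrane potential, mV (vectorised).
#' @param g Gate specification: list with `V_half` (mV), `slope_k`
#'   (mV, signed), `tau` (ms).
#' @return List with `x_inf` and `tau`.
#' @export
#' @examples
#' gate_inf_tau(-30, list(V_half = -35, slope_k = 5, tau = 2))
gate_inf_tau <- function(V, g) {
  list(x_inf = 1 / (1 + exp((g$V_half - V) / g$slope_k)),
       tau = rep_len(g$tau, length(V)))
}

#' Time derivatives of a single-compartment conductance-based cell
#'
#' Membrane equation
#' `C_m dV/dt = -g_leak (V - E_leak) - sum_channels gbar a^p h (V - E_rev) + I_total`,
#' first-order gate kinetics `dx/dt = (x_inf(V) - x) / tau_x`, and a linear
#' calcium pool `dCa/dt = -ca_rho * I_Ca - Ca / ca_tau`, where `I_Ca` is the
#' summed current of the calcium-carrying channels (inward current is
#' negative, so calcium rises on influx).
#'
#' @param state List with `V` (mV), `gates` (named numeric vector, all in
#'   \[0, 1\]) and `Ca` (uM, >= 0). Gate names are `<channel>_act` /
#'   `<channel>_inact`.
#' @param p Conductance cell parameters (see [default_parameters()] level C).
#' @param I_total External plus synaptic current, pA.
#' @return List of derivatives `dV`, `dgates`, `dCa` (per ms).
#' @export
conductance_cell_derivatives <- function(state, p, I_total = 0) {
  gates <- state$gates
  if (any(gates < -1e-9 | gates > 1 + 1e-9)) {
    stop("gate variable outside [0, 1]: ",
         paste(names(gates)[gates < -1e-9 | gates > 1 + 1e-9], collapse = ", "))
  }
  if (state$Ca < 0) stop("calcium concentration must be >= 0")
  V <- state$V
  I_channels <- 0
  I_ca <- 0
  dgates <- numeric(length(gates))
  names(dgates) <- names(gates)
  for (ch in p$channels) {
    a_name <- paste0(ch$name, "_act")
    act <- gates[[a_name]]
    gi <- gate_inf_tau(V, ch$activation)
    dgates[[a_name]] <- (gi$x_inf - act) / ch$activation$tau
    open <- act^ch$activation$exponent
    if (!is.null(ch$inactivation)) {
      h_name <- paste0(ch$name, "_inact")
      h <- gates[[h_name]]
      hi <- gate_inf_tau(V, ch$inactivation)
      dgates[[h_name]] <- (hi$x_inf - h) / ch$inactivation$tau
      open <- open * h
    }
    I <- ch$gbar * open * (V - ch$E_rev)
    I_channels <- I_channels + I
    if (isTRUE(ch$is_calcium_carrier)) I_ca <- I_ca + I
  }
  dV <- (-p$g_leak * (V - p$E_leak) - I_channels + I_total) / p$C_m
  dCa <- -p$ca_rho * I_ca - state$Ca / p$ca_tau
  list(dV = dV, dgates = dgates, dCa = dCa)
}

#' Forward-Euler step of a graded (analogue) synapse gate
#'
#' The activation variable relaxes towards a sigmoid function of the
#' presynaptic potential, `s_inf = 1 / (1 + exp((V_th_pre - V_pre) / delta))`,
#' with time constant `tau_s`, and is clamped to \[0, 1\]. Transmission is
#' continuous: no presynaptic spike is required.
#'
#' @param s Current activation in \[0, 1\] (vectorised).
#' @param V_pre Presynaptic membrane potential, mV.
#' @param p List with `V_th_pre` (mV), `delta` (mV, non-zero) and `tau_s` (ms).
#' @param dt Time step, ms.
#' @return Updated activation.
#' @export
graded_synapse_step <- function(s, V_pre, p, dt) {
  s_inf <- 1 / (1 + exp((p$V_th_pre - V_pre) / p$delta))
  pmin(pmax(s + dt * (s_inf - s) / p$tau_s, 0), 1)
}

#' Postsynaptic current of a chemical synapse
#'
#' Graded synapses drive `I = weight * s * (E_syn - V_post)`; spike-triggered
#' synapses drive `I = g * (E_syn - V_post)` where the conductance `g`
#' decays exponentially and is incremented by the connection weight at each
#' presynaptic spike (the increment is handled by the simulator). Currents
#' are signed into the postsynaptic cell, so depolarising current is
#' positive.
#'
#' @param kind `"graded"` or `"spike"`.
#' @param gate_or_conductance `s` in \[0, 1\] for graded synapses; the decaying
#'   conductance in nS for spike synapses.
#' @param weight Connection weight, nS (ignored for `"spike"`, whose
#'   conductance already includes it).
#' @param V_post Postsynaptic potential, mV.
#' @param E_syn Synaptic reversal potential, mV.
#' @return Current into the postsynaptic cell, pA.
#' @export
synapse_current <- function(kind, gate_or_conductance, weight, V_post, E_syn) {
  if (any(weight < 0)) stop("synaptic weight must be >= 0")
  g <- switch(kind,
              graded = weight * gate_or_conductance,
              spike = gate_or_conductance,
              stop("unknown synapse kind: ", kind))
  g * (E_syn - V_post)
}

#' Gap-junction currents between two coupled cells
#'
#' Ohmic electrical coupling: the current into cell a is
#' `weight * (V_b - V_a)` and the current into cell b is its negative, so
#' charge is conserved exactly.
#'
#' @param V_a,V_b Membrane potentials, mV (vectorised over junctions).
#' @param weight Junction conductance, nS (>= 0).
#' @return List with `I_into_a` and `I_into_b`, pA.
#' @export
gap_junction_current <- function(V_a, V_b, weight) {
  if (any(weight < 0)) stop("gap-junction weight must be >= 0")
  I <- weight * (V_b - V_a)
  list(I_into_a = I, I_into_b = -I)
}

#' Forward-Euler step of the firing-rate proxy ("activity") variable
#'
#' A leaky accumulator of spikes: decays with time constant `tau_activity`
#' and is incremented by a fixed amount at each spike of its cell. Used at
#' detail level B as a readout of cell activity; it does not feed back onto
#' the membrane dynamics.
#'
#' @param a Current activity (>= 0, vectorised).
#' @param spiked Logical: did the cell spike this step?
#' @param p List with `tau_activity` (ms) and `increment_per_spike`.
#' @param dt Time step, ms.
#' @return Updated activity.
#' @export
activity_step <- function(a, spiked, p, dt) {
  a * (1 - dt / p$tau_activity) + ifelse(spiked, p$increment_per_spike, 0)
}
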