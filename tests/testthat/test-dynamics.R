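test_that("a LIF cell at its leak reversal with no input stays put", {
  p <- lif_fixture()
  out <- lif_step(V = p$E_leak, I_total = 0, p = p, dt = 0.05)
  expect_equal(out$V, p$E_leak)
  expect_false(out$spiked)
})

test_that("subthreshold LIF charging matches the RC closed form within 1%", {
  p <- lif_fixture(V_thresh = 1e6)  # never spikes
  dt <- 0.05
  I <- 5  # pA; steady state E_leak + I/g = -50 mV
  steps <- seq_len(round(200 / dt))
  V <- p$E_leak
  trace <- numeric(length(steps))
  for (k in steps) {
    V <- lif_step(V, I, p, dt)$V
    trace[k] <- V
  }
  tt <- steps * dt
  exact <- p$E_leak + (I / p$g_leak) * (1 - exp(-tt * p$g_leak / p$C_m))
  expect_lt(max(abs(trace - exact)) / (I / p$g_leak), 0.01)
})

test_that("suprathreshold LIF inter-spike interval matches the closed form", {
  p <- lif_fixture()  # tau_m = 20 ms
  dt <- 0.05
  I <- 15  # pA; V_inf = -30 mV, above threshold
  tau_m <- p$C_m / p$g_leak
  isi_exact <- tau_m * log((I / p$g_leak + p$E_leak - p$V_reset) /
                           (I / p$g_leak + p$E_leak - p$V_thresh)) + p$t_refract
  V <- p$E_leak; refract <- -Inf; spikes <- c()
  for (k in seq_len(round(500 / dt))) {
    t <- (k - 1) * dt
    out <- lif_step(V, I, p, dt, refract, t)
    V <- out$V; refract <- out$refract_until
    if (out$spiked) spikes <- c(spikes, t + dt)
  }
  expect_gt(length(spikes), 5)
  isi_sim <- diff(spikes)
  expect_lt(max(abs(isi_sim - isi_exact)), dt + 1e-9)
})

test_that("gate steady state is a Boltzmann with midpoint V_half", {
  g <- list(V_half = -35, slope_k = 5, tau = 2)
  expect_equal(gate_inf_tau(-35, g)$x_inf, 0.5)
  expect_equal(gate_inf_tau(1e4, g)$x_inf, 1)
  expect_equal(gate_inf_tau(-30, g)$x_inf, 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(gate_inf_tau(-30, g)$x_inf, 0.7310586, tolerance = 1e-6)
  expect_equal(gate_inf_tau(-30, g)$tau, 2)
  # negative slope inverts the curve
  g_inv <- list(V_half = -35, slope_k = -5, tau = 2)
  expect_equal(gate_inf_tau(-30, g_inv)$x_inf + gate_inf_tau(-40, g_inv)$x_inf, 1)
})

test_that("a passive conductance cell is at equilibrium at its leak reversal", {
  p <- list(C_m = 10, g_leak = 0.3, E_leak = -60, ca_rho = 0.002, ca_tau = 60,
            spike_detect_threshold = 0,
            channels = list(list(
              name = "ca", gbar = 0, E_rev = 60, is_calcium_carrier = TRUE,
              activation = list(V_half = -25, slope_k = 5, tau = 2, exponent = 2))))
  st <- list(V = -60, gates = c(ca_act = gate_inf_tau(-60, p$channels[[1]]$activation)$x_inf),
             Ca = 0.5)
  d <- conductance_cell_derivatives(st, p, I_total = 0)
  expect_equal(d$dV, 0)
  expect_equal(unname(d$dgates), 0)
  expect_equal(d$dCa, -0.5 / 60)
})

test_that("voltage-clamped gates relax exponentially to x_inf within 0.5%", {
  gate <- list(V_half = -30, slope_k = 6, tau = 12, exponent = 1)
  p <- list(C_m = 10, g_leak = 0.3, E_leak = -60, ca_rho = 0, ca_tau = 50,
            spike_detect_threshold = 0,
            channels = list(list(name = "k", gbar = 1, E_rev = -80,
                                 is_calcium_carrier = FALSE, activation = gate)))
  V_clamp <- -20
  dt <- 0.05
  x <- gate_inf_tau(-60, gate)$x_inf
  x0 <- x
  tt <- seq_len(round(60 / dt)) * dt
  trace <- numeric(length(tt))
  for (k in seq_along(tt)) {
    d <- conductance_cell_derivatives(list(V = V_clamp, gates = c(k_act = x), Ca = 0), p)
    x <- x + dt * d$dgates[["k_act"]]
    trace[k] <- x
  }
  x_inf <- gate_inf_tau(V_clamp, gate)$x_inf
  exact <- x_inf + (x0 - x_inf) * exp(-tt / gate$tau)
  expect_lt(max(abs(trace - exact)) / abs(x_inf - x0), 0.005)
})

test_that("the calcium pool decays exponentially when no calcium flows", {
  p <- list(C_m = 10, g_leak = 0.3, E_leak = -60, ca_rho = 0.002, ca_tau = 40,
            spike_detect_threshold = 0, channels = list())
  dt <- 0.05
  Ca <- 2
  tt <- seq_len(round(80 / dt)) * dt
  trace <- numeric(length(tt))
  for (k in seq_along(tt)) {
    d <- conductance_cell_derivatives(list(V = -60, gates = numeric(0), Ca = Ca), p)
    Ca <- Ca + dt * d$dCa
    trace[k] <- Ca
  }
  exact <- 2 * exp(-tt / 40)
  expect_lt(max(abs(trace - exact)) / 2, 0.005)
})

test_that("gate states outside [0,1] are rejected", {
  p <- list(C_m = 10, g_leak = 0.3, E_leak = -60, ca_rho = 0, ca_tau = 50,
            spike_detect_threshold = 0,
            channels = list(list(name = "k", gbar = 1, E_rev = -80,
                                 is_calcium_carrier = FALSE,
                                 activation = list(V_half = -30, slope_k = 6,
                                                   tau = 12, exponent = 1))))
  expect_error(conductance_cell_derivatives(
    list(V = -60, gates = c(k_act = 1.01), Ca = 0), p), "k_act")
})

test_that("graded synapse fixed point, relaxation and symmetry", {
  p <- list(V_th_pre = -35, delta = 4, tau_s = 30)
  expect_equal(graded_synapse_step(0.5, -35, p, 0.05), 0.5)

  # strong depolarisation: s -> 1 exponentially with time constant tau_s
  dt <- 0.05
  s <- 0
  tt <- seq_len(round(120 / dt)) * dt
  trace <- numeric(length(tt))
  for (k in seq_along(tt)) {
    s <- graded_synapse_step(s, 40, p, dt)  # s_inf ~ 1 to 9 decimal places
    trace[k] <- s
  }
  exact <- 1 - exp(-tt / p$tau_s)
  expect_lt(max(abs(trace - exact)), 0.005)

  # flipping delta mirrors the activation curve about V_th_pre
  for (V in c(-50, -40, -35, -30, -10)) {
    s_pos <- 1 / (1 + exp((p$V_th_pre - V) / p$delta))
    V_mirror <- 2 * p$V_th_pre - V
    s_mirror <- 1 / (1 + exp((p$V_th_pre - V_mirror) / p$delta))
    expect_equal(s_pos + s_mirror, 1, tolerance = 1e-12)
  }
})

test_that("synaptic currents follow driving force and unit arithmetic", {
  expect_equal(synapse_current("graded", 1, 0.13, V_post = -10, E_syn = 0), 1.3)
  expect_equal(synapse_current("graded", 0.7, 2, V_post = -70, E_syn = -70), 0)
  expect_equal(synapse_current("spike", 0, 1, V_post = -60, E_syn = 0), 0)
  expect_error(synapse_current("graded", 0.5, -1, -60, 0), ">= 0")
})

test_that("gap-junction currents are ohmic and conserve charge exactly", {
  out <- gap_junction_current(-60, -60, 1)
  expect_equal(out$I_into_a, 0)
  expect_equal(gap_junction_current(-60, -50, 1)$I_into_a, 10)
  set.seed(1)
  for (i in 1:20) {
    Va <- stats::runif(1, -80, 20); Vb <- stats::runif(1, -80, 20)
    w <- stats::runif(1, 0, 5)
    out <- gap_junction_current(Va, Vb, w)
    expect_identical(out$I_into_a + out$I_into_b, 0)
  }
})

test_that("the activity proxy decays between spikes and tracks rate", {
  p <- list(tau_activity = 200, increment_per_spike = 0.1)
  expect_equal(activity_step(0, FALSE, p, 0.05), 0)
  # pure decay over 200 ms matches the linear ODE solution, exp(-1)
  dt <- 0.05
  a <- 1
  for (k in 1:4000) a <- activity_step(a, FALSE, p, dt)
  expect_equal(a, exp(-1), tolerance = 0.01)
  # periodic spiking at rate r: cycle-averaged a settles at increment * r * tau
  r <- 0.02  # spikes per ms
  steps_per_spike <- round(1 / r / dt)
  a <- 0; acc <- c()
  for (k in 1:40000) {
    a <- activity_step(a, (k %% steps_per_spike) == 0, p, dt)
    if (k > 40000 - steps_per_spike) acc <- c(acc, a)
  }
  expect_equal(mean(acc), p$increment_per_spike * r * p$tau_activity,
               tolerance = 0.05)
})

test_that("gates and synapse activations stay in [0,1] under random drive", {
  set.seed(99)
  for (rep in 1:10) {
    gate <- list(V_half = stats::runif(1, -50, -10),
                 slope_k = sample(c(-1, 1), 1) * stats::runif(1, 2, 15),
                 tau = stats::runif(1, 0.5, 50), exponent = sample(1:4, 1))
    syn <- list(V_th_pre = stats::runif(1, -50, -20),
                delta = stats::runif(1, 1, 10), tau_s = stats::runif(1, 5, 60))
    x <- stats::runif(1); s <- stats::runif(1)
    dt <- 0.05
    for (k in 1:2000) {
      V <- stats::runif(1, -100, 40)  # erratic voltage excursions
      gi <- gate_inf_tau(V, gate)
      x <- x + dt * (gi$x_inf - x) / gi$tau
      s <- graded_synapse_step(s, V, syn, dt)
      expect_true(x >= -1e-9 && x <= 1 + 1e-9)
      expect_true(s >= 0 && s <= 1)
    }
  }
})

test_that("Euler integration of a scalar linear ODE converges at first order", {
  gate <- list(V_half = -30, slope_k = 6, tau = 10)
  target <- gate_inf_tau(-20, gate)$x_inf
  final_x <- function(dt) {
    x <- 0
    for (k in seq_len(round(20 / dt))) x <- x + dt * (target - x) / gate$tau
    x
  }
  exact <- target * (1 - exp(-20 / gate$tau))
  e1 <- abs(final_x(0.2) - exact)
  e2 <- abs(final_x(0.1) - exact)
  e3 <- abs(final_x(0.05) - exact)
  expect_equal(e2 / e1, 0.5, tolerance = 0.1)
  expect_equal(e3 / e2, 0.5, tolerance = 0.1)
})
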