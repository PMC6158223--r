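# Internal: flatten a network_model into index arrays for the Euler loop.
compile_network <- function(net) {
  cells <- net$cells
  n <- nrow(cells)
  idx_of <- stats::setNames(seq_len(n), cells$name)
  p <- net$params

  groups <- list()
  for (gname in c("neuron", "muscle")) {
    gidx <- which(cells$model_group == gname)
    if (length(gidx) == 0) next
    cp <- if (gname == "muscle") p$muscle_params else p$neuron_params
    g <- list(name = gname, idx = gidx, model = cp$model, p = cp)
    if (cp$model == "conductance") {
      gates <- list()   # per gate column: V_half, slope_k, tau
      chans <- list()   # per channel: act column, inact column (0 if none)
      for (ch in cp$channels) {
        gates[[length(gates) + 1]] <- c(ch$activation$V_half, ch$activation$slope_k,
                                        ch$activation$tau)
        act_col <- length(gates)
        inact_col <- 0L
        if (!is.null(ch$inactivation)) {
          gates[[length(gates) + 1]] <- c(ch$inactivation$V_half,
                                          ch$inactivation$slope_k, ch$inactivation$tau)
          inact_col <- length(gates)
        }
        chans[[length(chans) + 1]] <- list(
          gbar = ch$gbar, E_rev = ch$E_rev, exponent = ch$activation$exponent,
          act = act_col, inact = inact_col, is_ca = isTRUE(ch$is_calcium_carrier))
      }
      gm <- do.call(rbind, gates)
      g$gate_V_half <- gm[, 1]; g$gate_k <- gm[, 2]; g$gate_tau <- gm[, 3]
      g$channels <- chans
      g$n_gates <- nrow(gm)
    }
    groups[[gname]] <- g
  }

  syn <- net$synapses
  chem <- syn[syn$kind %in% c("chem_exc", "chem_inh"), ]
  chem_kind <- if (nrow(chem) > 0) p$exc_syn$kind else "graded"
  chem_c <- list(
    n = nrow(chem),
    pre = unname(idx_of[chem$pre]), post = unname(idx_of[chem$post]),
    weight = chem$weight,
    E_syn = ifelse(chem$kind == "chem_inh", p$inh_syn$E_syn, p$exc_syn$E_syn),
    kind = chem_kind)
  if (chem_kind == "graded") {
    chem_c$V_th_pre <- ifelse(chem$kind == "chem_inh", p$inh_syn$V_th_pre, p$exc_syn$V_th_pre)
    chem_c$delta <- ifelse(chem$kind == "chem_inh", p$inh_syn$delta, p$exc_syn$delta)
    chem_c$tau <- ifelse(chem$kind == "chem_inh", p$inh_syn$tau_s, p$exc_syn$tau_s)
  } else {
    chem_c$tau <- ifelse(chem$kind == "chem_inh", p$inh_syn$tau_decay, p$exc_syn$tau_decay)
  }

  gap <- syn[syn$kind == "gap", ]
  gap_c <- list(n = nrow(gap), a = unname(idx_of[gap$pre]),
                b = unname(idx_of[gap$post]), weight = gap$weight)

  st <- net$stimuli
  stim_c <- list(
    n = nrow(st), target = unname(idx_of[st$target]),
    amplitude = st$amplitude, onset = st$onset,
    pulse_duration = st$pulse_duration,
    period = ifelse(is.na(st$period), Inf, st$period),
    n_pulses = st$n_pulses,
    unique_targets = !anyDuplicated(st$target))

  list(n = n, names = cells$name, groups = groups, chem = chem_c, gap = gap_c,
       stim = stim_c, params = p)
}

# Deterministic equilibrium state: V at leak reversal, gates at their steady
# state for that voltage, synapses fully closed, calcium pool empty.
compiled_initial_state <- function(cm) {
  st <- list(V = numeric(cm$n), Ca = numeric(cm$n),
             gates = list(), s = numeric(cm$chem$n),
             refract_until = rep(-Inf, cm$n),
             activity = numeric(cm$n),
             prev_spiked = logical(cm$n),
             last_spike = rep(-Inf, cm$n))
  for (g in cm$groups) {
    st$V[g$idx] <- g$p$E_leak
    if (g$model == "conductance") {
      X <- matrix(0, nrow = length(g$idx), ncol = g$n_gates)
      for (j in seq_len(g$n_gates)) {
        X[, j] <- 1 / (1 + exp((g$gate_V_half[j] - g$p$E_leak) / g$gate_k[j]))
      }
      st$gates[[g$name]] <- X
    }
  }
  st
}

#' Initial state of a network model
#'
#' Every cell starts at its leak reversal potential with gates at their
#' steady-state value for that voltage, synaptic gates and conductances at
#' zero, and an empty calcium pool. The assignment is deterministic, and for
#' an unstimulated passive network it is an equilibrium of the dynamics.
#'
#' @param net A `network_model`.
#' @return List with `V` (named, mV), `Ca` (named, uM), `gates` (named list of
#'   matrices per cell group) and `s` (per chemical synapse).
#' @export
initial_state <- function(net) {
  cm <- compile_network(net)
  st <- compiled_initial_state(cm)
  names(st$V) <- cm$names
  names(st$Ca) <- cm$names
  st[c("V", "Ca", "gates", "s")]
}

#' Simulate a network model with a fixed-step forward-Euler integrator
#'
#' All state variables advance synchronously: stimulus, synaptic and
#' gap-junction currents for a step are computed from the previous step's
#' state, then every cell is advanced, so results do not depend on cell
#' ordering. Spike events (threshold crossings of LIF cells, or upward
#' crossings of the spike-detection threshold in conductance-based cells,
#' with a 1 ms minimum inter-event interval) take effect on spike-triggered
#' synapses at the next step. The dynamics are deterministic: identical
#' inputs give bit-identical results.
#'
#' @param net A `network_model`.
#' @param duration Simulated time, ms (>= 0; 0 records the initial state only).
#' @param dt Time step, ms, in (0, 1].
#' @param record Any of `"voltage"`, `"calcium"`, `"spikes"`.
#' @param record_every Sample every this many steps (1 = every step).
#' @return A `simulation_result`: list with `times` (ms), `V` (cells x samples
#'   matrix, mV), `Ca` (conductance-based cells x samples, uM), `spikes`
#'   (named list of event times), `activity` (firing-rate proxy, level B),
#'   `dt` and `duration`.
#' @export
simulate_network <- function(net, duration, dt = 0.05,
                             record = c("voltage", "calcium", "spikes"),
                             record_every = 1L) {
  if (duration < 0) stop("duration must be >= 0")
  if (dt <= 0 || dt > 1) stop("dt must lie in (0, 1] ms")
  record <- match.arg(record, several.ok = TRUE)
  cm <- compile_network(net)
  st <- compiled_initial_state(cm)
  n_steps <- round(duration / dt)

  ca_cells <- sort(unlist(lapply(cm$groups, function(g)
    if (g$model == "conductance") g$idx else integer())))
  rec_idx <- seq(0, n_steps, by = record_every)
  n_samp <- length(rec_idx)
  times <- rec_idx * dt
  V_rec <- if ("voltage" %in% record) matrix(NA_real_, cm$n, n_samp,
             dimnames = list(cm$names, NULL)) else NULL
  Ca_rec <- if ("calcium" %in% record && length(ca_cells) > 0)
    matrix(NA_real_, length(ca_cells), n_samp,
           dimnames = list(cm$names[ca_cells], NULL)) else NULL
  spike_events <- list()

  # Per-group constant unpacking
  grp <- cm$groups
  chem <- cm$chem; gap <- cm$gap; stim <- cm$stim
  level_b <- cm$params$level == "B"
  act_p <- cm$params$activity
  syn_is_graded <- chem$kind == "graded"
  g_syn <- numeric(chem$n)   # decaying conductance of spike synapses

  sample_col <- 1L
  take_sample <- function(col) {
    if (!is.null(V_rec)) V_rec[, col] <<- st$V
    if (!is.null(Ca_rec)) Ca_rec[, col] <<- st$Ca[ca_cells]
  }
  take_sample(1L)

  for (step in seq_len(n_steps)) {
    t <- (step - 1) * dt
    I <- numeric(cm$n)

    # --- stimuli ------------------------------------------------------
    if (stim$n > 0) {
      te <- t - stim$onset
      phase <- te %% stim$period
      phase[!is.finite(stim$period)] <- te[!is.finite(stim$period)]
      pulse_i <- ifelse(is.finite(stim$period), te %/% stim$period, 0)
      on <- te >= 0 & phase < stim$pulse_duration & pulse_i < stim$n_pulses
      if (any(on)) {
        if (stim$unique_targets) {
          I[stim$target[on]] <- I[stim$target[on]] + stim$amplitude[on]
        } else {
          for (j in which(on)) I[stim$target[j]] <- I[stim$target[j]] + stim$amplitude[j]
        }
      }
    }

    # --- synaptic and gap currents from previous-step state -----------
    if (chem$n > 0) {
      g_edge <- if (syn_is_graded) chem$weight * st$s else g_syn
      I_edge <- g_edge * (chem$E_syn - st$V[chem$post])
      acc <- rowsum(I_edge, chem$post)
      I[as.integer(rownames(acc))] <- I[as.integer(rownames(acc))] + acc[, 1]
    }
    if (gap$n > 0) {
      I_g <- gap$weight * (st$V[gap$b] - st$V[gap$a])
      acc_a <- rowsum(I_g, gap$a)
      I[as.integer(rownames(acc_a))] <- I[as.integer(rownames(acc_a))] + acc_a[, 1]
      acc_b <- rowsum(-I_g, gap$b)
      I[as.integer(rownames(acc_b))] <- I[as.integer(rownames(acc_b))] + acc_b[, 1]
    }

    # --- synapse state update (uses previous-step V and spikes) -------
    if (chem$n > 0) {
      if (syn_is_graded) {
        s_inf <- 1 / (1 + exp((chem$V_th_pre - st$V[chem$pre]) / chem$delta))
        st$s <- pmin(pmax(st$s + dt * (s_inf - st$s) / chem$tau, 0), 1)
      } else {
        g_syn <- g_syn * (1 - dt / chem$tau) +
          chem$weight * st$prev_spiked[chem$pre]
      }
    }

    # --- advance cells ------------------------------------------------
    spiked <- logical(cm$n)
    for (g in grp) {
      gi <- g$idx
      Vg <- st$V[gi]
      if (g$model == "lif") {
        res <- lif_step(Vg, I[gi], g$p, dt, st$refract_until[gi], t)
        st$V[gi] <- res$V
        spiked[gi] <- res$spiked
        st$refract_until[gi] <- res$refract_until
      } else {
        X <- st$gates[[g$name]]
        I_chan <- numeric(length(gi))
        I_ca <- numeric(length(gi))
        for (ch in g$channels) {
          open <- X[, ch$act]^ch$exponent
          if (ch$inact > 0) open <- open * X[, ch$inact]
          I_c <- ch$gbar * open * (Vg - ch$E_rev)
          I_chan <- I_chan + I_c
          if (ch$is_ca) I_ca <- I_ca + I_c
        }
        for (j in seq_len(g$n_gates)) {
          x_inf <- 1 / (1 + exp((g$gate_V_half[j] - Vg) / g$gate_k[j]))
          X[, j] <- X[, j] + dt * (x_inf - X[, j]) / g$gate_tau[j]
        }
        X[X < 0] <- 0; X[X > 1] <- 1
        st$gates[[g$name]] <- X
        V_new <- Vg + dt * (-g$p$g_leak * (Vg - g$p$E_leak) - I_chan + I[gi]) / g$p$C_m
        Ca_new <- st$Ca[gi] + dt * (-g$p$ca_rho * I_ca - st$Ca[gi] / g$p$ca_tau)
        Ca_new[Ca_new < 0] <- 0
        thr <- g$p$spike_detect_threshold
        crossed <- Vg < thr & V_new >= thr & (t - st$last_spike[gi]) >= 1
        spiked[gi] <- crossed
        st$last_spike[gi][crossed] <- t
        st$V[gi] <- V_new
        st$Ca[gi] <- Ca_new
      }
    }
    if (anyNA(st$V) || any(is.infinite(st$V))) {
      bad <- which(!is.finite(st$V))[1]
      stop(sprintf("non-finite membrane potential in cell %s at t = %g ms",
                   cm$names[bad], t + dt))
    }
    if (level_b) st$activity <- activity_step(st$activity, spiked, act_p, dt)
    if (any(spiked)) {
      spike_events[[length(spike_events) + 1]] <- list(t = t + dt, cells = which(spiked))
    }
    st$prev_spiked <- spiked

    if (step %% record_every == 0) {
      sample_col <- sample_col + 1L
      take_sample(sample_col)
    }
  }

  spikes <- stats::setNames(vector("list", cm$n), cm$names)
  for (i in seq_len(cm$n)) spikes[[i]] <- numeric(0)
  for (ev in spike_events) {
    for (ci in ev$cells) spikes[[ci]] <- c(spikes[[ci]], ev$t)
  }
  if (!"spikes" %in% record) spikes <- NULL

  structure(list(times = times, V = V_rec, Ca = Ca_rec, spikes = spikes,
                 activity = if (level_b) stats::setNames(st$activity, cm$names) else NULL,
                 dt = dt, duration = duration, level = cm$params$level,
                 cell_names = cm$names, final_state = st),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", length(x$cell_names), "cells,",
      sprintf("%g ms at dt = %g ms (%d samples)", x$duration, x$dt, length(x$times)), "\n")
  if (!is.null(x$spikes)) cat("  spikes:", sum(lengths(x$spikes)), "\n")
  invisible(x)
}

#' Tidy a simulation result into a long trace table
#'
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @return Tibble with columns `time` (ms), `cell`, `variable`
#'   (`"v"` or `"ca"`) and `value`.
#' @export
tidy.simulation_result <- function(x, ...) {
  out <- list()
  if (!is.null(x$V)) {
    out$v <- tibble::tibble(
      time = rep(x$times, each = nrow(x$V)),
      cell = rep(rownames(x$V), times = length(x$times)),
      variable = "v", value = as.vector(x$V))
  }
  if (!is.null(x$Ca)) {
    out$ca <- tibble::tibble(
      time = rep(x$times, each = nrow(x$Ca)),
      cell = rep(rownames(x$Ca), times = length(x$times)),
      variable = "ca", value = as.vector(x$Ca))
  }
  dplyr::bind_rows(out)
}

#' @export
glance.simulation_result <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$cell_names),
    duration = x$duration, dt = x$dt,
    n_samples = length(x$times),
    n_spikes = if (!is.null(x$spikes)) sum(lengths(x$spikes)) else NA_integer_,
    level = x$level)
}

#' Plot recorded traces of a simulation
#'
#' Membrane-potential (and optionally calcium) traces for a selection of
#' cells, one facet per variable.
#'
#' @param object A `simulation_result`.
#' @param cells Cell names to show (default: up to 8 recorded cells).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.simulation_result <- function(object, cells = NULL, ...) {
  df <- tidy(object)
  if (is.null(cells)) cells <- utils::head(unique(df$cell), 8)
  df <- df[df$cell %in% cells, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$cell)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$variable, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(v = "membrane potential (mV)", ca = "[Ca2+] (uM)"))) +
    ggplot2::labs(x = "time (ms)", y = NULL, colour = "cell") +
    ggplot2::theme_minimal()
}
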