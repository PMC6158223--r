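# Motor neuron classes of the forward-locomotion circuit.
locomotion_neuron_names <- function() {
  list(AVB = c("AVBL", "AVBR"),
       DB = sprintf("DB%d", 1:7), VB = sprintf("VB%d", 1:11),
       DD = sprintf("DD%d", 1:6), VD = sprintf("VD%d", 1:13))
}

# Contiguous, anatomically ordered muscle-index blocks for a motor neuron
# class: n blocks covering indices lo..hi, consecutive blocks sharing one
# index. Returns a two-column matrix (lo, hi) per neuron.
class_blocks <- function(n, lo = 8, hi = 24) {
  b <- round(seq(lo, hi, length.out = n + 1))
  cbind(lo = b[-(n + 1)], hi = b[-1])
}

#' Default innervation map of the locomotion circuit
#'
#' Assigns each B- and D-type motor neuron a contiguous, anatomically
#' ordered block of muscles on its own side of the body (dorsal neurons to
#' the two MD rows, ventral neurons to the two MV rows), consecutive neurons
#' overlapping by one muscle, covering muscle indices 8-24. Indices 1-7 (the
#' head muscles) are driven directly by the stimulus protocol rather than by
#' motor neurons, and MVL24 is excluded from the map, so exactly 95 of the 96
#' muscles receive input. A measured wiring table can be supplied instead via
#' [read_innervation_csv()].
#'
#' @return Tibble with columns `neuron`, `muscle`.
#' @export
default_innervation_map <- function() {
  nn <- locomotion_neuron_names()
  rows <- list()
  add_class <- function(neurons, quadrants) {
    blocks <- class_blocks(length(neurons))
    purrr::map_dfr(seq_along(neurons), function(i) {
      idx <- blocks[i, "lo"]:blocks[i, "hi"]
      tibble::tibble(neuron = neurons[i],
                     muscle = as.vector(outer(quadrants, idx, sprintf,
                                              fmt = "%s%02d")))
    })
  }
  out <- dplyr::bind_rows(
    add_class(nn$DB, c("MDL", "MDR")),
    add_class(nn$DD, c("MDL", "MDR")),
    add_class(nn$VB, c("MVL", "MVR")),
    add_class(nn$VD, c("MVL", "MVR")))
  out[out$muscle != "MVL24", ]
}

#' Read an innervation table from CSV
#'
#' One row per motor-neuron-to-muscle edge, columns `neuron` and `muscle`.
#'
#' @param file Path to the CSV file.
#' @return Tibble with columns `neuron`, `muscle`.
#' @export
read_innervation_csv <- function(file) {
  x <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(c("neuron", "muscle"), names(x))
  if (length(missing_cols) > 0) {
    stop("innervation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tibble::tibble(neuron = x$neuron, muscle = x$muscle)
}

#' Configuration of the forward-locomotion circuit
#'
#' Bundles the drive and coupling constants of the circuit. The central
#' pattern generator (CPG) is approximated by periodic current pulses into
#' the first B-type motor neurons (DB1 and VB1), phase-shifted between the
#' dorsal and ventral sides; AVB command neurons receive a tonic current for
#' the whole run; the head muscles (indices 1-7 of each quadrant) are driven
#' directly by synchronised pulses at the CPG period. None of these
#' amplitudes is a measured quantity: they are model constants chosen so the
#' default circuit produces a robust head-to-tail wave, and all are tunable.
#'
#' @param cpg_period CPG pulse period, ms. The default of 1250 ms gives four
#'   full body waves in a 5 s run.
#' @param cpg_pulse_duration CPG pulse width, ms (< `cpg_period`).
#' @param cpg_amplitude CPG pulse current, pA.
#' @param dorsoventral_delay Phase shift of the ventral drive relative to the
#'   dorsal, ms. Default half a period: alternating dorsal/ventral bends.
#' @param head_stim_amplitude Direct head-muscle pulse current, pA.
#' @param head_phase Offset of the dorsal head-muscle pulses relative to the
#'   CPG, ms.
#' @param avb_amplitude Tonic AVB current, pA.
#' @param proprio_gain Weight of the feed-forward excitatory coupling between
#'   successive B neurons, nS (the stretch-receptor stand-in).
#' @param uniform_weight Shared weight of every synaptic connection, nS.
#' @param innervation_map Tibble (`neuron`, `muscle`); defaults to
#'   [default_innervation_map()].
#' @return A `locomotion_config` list.
#' @export
locomotion_config <- function(cpg_period = 1250, cpg_pulse_duration = 300,
                              cpg_amplitude = 20, dorsoventral_delay = cpg_period / 2,
                              head_stim_amplitude = 25, head_phase = 0,
                              avb_amplitude = 8, proprio_gain = 0.6,
                              uniform_weight = 0.1,
                              innervation_map = default_innervation_map()) {
  if (!(cpg_period > cpg_pulse_duration && cpg_pulse_duration > 0)) {
    stop("need cpg_period > cpg_pulse_duration > 0")
  }
  if (proprio_gain < 0 || uniform_weight < 0) stop("gains must be >= 0")
  structure(list(cpg_period = cpg_period, cpg_pulse_duration = cpg_pulse_duration,
                 cpg_amplitude = cpg_amplitude, dorsoventral_delay = dorsoventral_delay,
                 head_stim_amplitude = head_stim_amplitude, head_phase = head_phase,
                 avb_amplitude = avb_amplitude, proprio_gain = proprio_gain,
                 uniform_weight = uniform_weight, innervation_map = innervation_map),
            class = "locomotion_config")
}

#' Build the forward-locomotion circuit
#'
#' Instantiates the circuit of 39 neurons — the AVB command pair, 18 B-type
#' motor neurons (DB1-DB7, VB1-VB11) and 19 D-type inhibitory motor neurons
#' (DD1-DD6, VD1-VD13) — plus the 96 body-wall muscles, wired by class:
#' AVB makes gap junctions with every B neuron; consecutive B neurons of each
#' side are gap-coupled in a chain; B neurons excite their muscles and D
#' neurons inhibit theirs (per the innervation map); DB neurons excite VD and
#' inhibit DD neurons, and VB neurons excite DD and inhibit VD neurons, in
#' the body region they share. Every connection carries the same weight.
#' Stimuli: tonic AVB current, antiphase periodic pulses into DB1 and VB1,
#' and synchronised periodic pulses into the first seven muscles of each
#' quadrant.
#'
#' Requires a conductance-based parameter set (level C or C1); the
#' proprioceptive coupling between successive B neurons is added separately
#' by [add_proprioceptive_coupling()].
#'
#' @param params A `parameter_set`, level C or C1.
#' @param cfg A [locomotion_config()].
#' @return A `network_model`.
#' @export
build_forward_locomotion <- function(params = default_parameters("C1"),
                                     cfg = locomotion_config()) {
  params <- validate_parameter_set(unclass(params))
  if (!params$level %in% c("C", "C1")) {
    stop("the locomotion circuit requires conductance-based cells (level C or C1)")
  }
  nn <- locomotion_neuron_names()
  neurons <- unlist(nn, use.names = FALSE)
  lay <- layout_muscles()
  cells <- dplyr::bind_rows(
    tibble::tibble(name = neurons,
                   cell_class = c("interneuron", "interneuron",
                                  rep("motorneuron", 18 + 19)),
                   neurotransmitter = c(rep("Acetylcholine", 2 + 18),
                                        rep("GABA", 19))),
    tibble::tibble(name = lay$name, cell_class = "muscle",
                   neurotransmitter = "UNKNOWN"))
  cells <- dplyr::bind_cols(cells[, c("name", "cell_class", "neurotransmitter")],
                            default_positions(cells))

  w <- cfg$uniform_weight
  edge <- function(pre, post, kind) {
    tibble::tibble(pre = pre, post = post, kind = kind, weight = w)
  }
  b_neurons <- c(nn$DB, nn$VB)
  syn <- list(
    # AVB <-> B gap junctions
    edge(rep(nn$AVB, each = length(b_neurons)),
         rep(b_neurons, times = 2), "gap"),
    # chain gap junctions between consecutive B neurons
    edge(nn$DB[-length(nn$DB)], nn$DB[-1], "gap"),
    edge(nn$VB[-length(nn$VB)], nn$VB[-1], "gap"))

  # neuron -> muscle edges from the innervation map
  imap <- cfg$innervation_map
  unknown <- setdiff(imap$muscle, lay$name)
  if (length(unknown) > 0) stop("innervation map names unknown muscles: ",
                                paste(unknown, collapse = ", "))
  cls <- substr(imap$neuron, 1, 2)
  syn <- c(syn, list(
    edge(imap$neuron[cls %in% c("DB", "VB")], imap$muscle[cls %in% c("DB", "VB")],
         "chem_exc"),
    edge(imap$neuron[cls %in% c("DD", "VD")], imap$muscle[cls %in% c("DD", "VD")],
         "chem_inh")))

  # crossed class-to-class edges where body regions overlap
  spans <- function(neurons) {
    bl <- class_blocks(length(neurons))
    tibble::tibble(neuron = neurons, lo = bl[, "lo"], hi = bl[, "hi"])
  }
  cross <- function(from, to, kind) {
    a <- spans(nn[[from]]); b <- spans(nn[[to]])
    pairs <- tidyr::crossing(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    keep <- pmax(a$lo[pairs$i], b$lo[pairs$j]) <= pmin(a$hi[pairs$i], b$hi[pairs$j])
    edge(a$neuron[pairs$i[keep]], b$neuron[pairs$j[keep]], kind)
  }
  syn <- c(syn, list(
    cross("DB", "VD", "chem_exc"), cross("DB", "DD", "chem_inh"),
    cross("VB", "DD", "chem_exc"), cross("VB", "VD", "chem_inh")))

  net <- new_network_model(
    dplyr::mutate(cells, model_group = ifelse(.data$cell_class == "muscle",
                                              "muscle", "neuron")),
    dplyr::bind_rows(syn), empty_stimuli(), params)

  # stimuli: tonic AVB, antiphase CPG pulses into DB1/VB1, head-muscle pulses
  for (avb in nn$AVB) {
    net <- add_stimulus(net, avb, cfg$avb_amplitude, onset = 0,
                        pulse_duration = Inf)
  }
  net <- add_stimulus(net, "DB1", cfg$cpg_amplitude, onset = 0,
                      pulse_duration = cfg$cpg_pulse_duration,
                      period = cfg$cpg_period)
  net <- add_stimulus(net, "VB1", cfg$cpg_amplitude,
                      onset = cfg$dorsoventral_delay,
                      pulse_duration = cfg$cpg_pulse_duration,
                      period = cfg$cpg_period)
  head_muscles <- lay$name[lay$index <= 7]
  for (m in head_muscles) {
    net <- add_stimulus(net, m, cfg$head_stim_amplitude,
                        onset = cfg$head_phase +
                          if (grepl("^MD", m)) 0 else cfg$dorsoventral_delay,
                        pulse_duration = cfg$cpg_pulse_duration,
                        period = cfg$cpg_period)
  }
  net
}

#' Add proprioceptive coupling along the B-type chains
#'
#' A feed-forward excitatory stand-in for stretch-receptor signalling: each
#' DB and VB neuron excites its posterior neighbour (anterior to posterior
#' only) through a graded connection of the given weight, so activity
#' initiated at the head propagates down the chain.
#'
#' @param net A `network_model` containing the B-type chains.
#' @param gain Connection weight, nS.
#' @return The network with `n_DB - 1 + n_VB - 1` added excitatory edges.
#' @export
add_proprioceptive_coupling <- function(net, gain) {
  if (gain < 0) stop("gain must be >= 0")
  chains <- list(sort_chain(grep("^DB[0-9]+$", net$cells$name, value = TRUE)),
                 sort_chain(grep("^VB[0-9]+$", net$cells$name, value = TRUE)))
  for (chain in chains) {
    if (length(chain) < 2) next
    net$synapses <- dplyr::bind_rows(net$synapses, tibble::tibble(
      pre = chain[-length(chain)], post = chain[-1],
      kind = "chem_exc", weight = gain))
  }
  net
}

sort_chain <- function(names) {
  names[order(as.integer(gsub("[^0-9]", "", names)))]
}

#' Muscle quadrant ordering for wave analysis
#'
#' The four quadrant rows in anterior-to-posterior order, with MVL24 (which
#' receives no input in the default circuit and stays silent) excluded.
#'
#' @return Named list of character vectors, one per quadrant.
#' @export
locomotion_muscle_order <- function() {
  lay <- layout_muscles()
  out <- split(lay$name, lay$quadrant)
  out$MVL <- setdiff(out$MVL, "MVL24")
  out[c("MDL", "MDR", "MVL", "MVR")]
}

# Local maxima of y above a prominence threshold relative to the trace range,
# at least min_dist apart (earliest kept).
find_ca_peaks <- function(tt, y, prom_frac = 0.5, min_dist = 50) {
  n <- length(y)
  if (n < 3) return(numeric(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  rng <- range(y)
  if (diff(rng) <= 0) return(numeric(0))
  cand <- cand[y[cand] >= rng[1] + prom_frac * diff(rng)]
  if (length(cand) == 0) return(numeric(0))
  kept <- cand[1]
  for (i in cand[-1]) if (tt[i] - tt[kept[length(kept)]] >= min_dist) kept <- c(kept, i)
  tt[kept]
}

circular_mean_phase <- function(dt_values, period) {
  ang <- 2 * pi * dt_values / period
  (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1
}

#' Travelling-wave metrics from muscle calcium traces
#'
#' Detects per-muscle calcium peaks after a settling period (local maxima
#' above a prominence threshold relative to the trace range) and summarises
#' the spatiotemporal pattern: the head-to-tail propagation slope (per
#' quadrant, least-squares fit of the first post-settle peak time against
#' muscle index — positive means the wave travels towards the tail), the
#' oscillation frequency (median inter-peak interval of a reference muscle),
#' and the dorsoventral and left-right phase differences (circular means of
#' the paired first-peak time differences, as a fraction of the period).
#'
#' @param result A `simulation_result` with calcium recorded, or a data frame
#'   with a `time` column (ms) and one numeric column per muscle.
#' @param muscle_order Named list of muscle-name vectors per quadrant in
#'   anterior-to-posterior order; defaults to [locomotion_muscle_order()]
#'   restricted to recorded muscles.
#' @param settle_time Discard activity before this time, ms.
#' @param prom_frac Peak prominence threshold as a fraction of the
#'   post-settle trace range.
#' @param min_peak_dist Minimum separation between detected peaks, ms.
#' @return A `wave_metrics` object: list with `peaks` (tibble: muscle,
#'   quadrant, index, first_peak, n_peaks), `slopes` (tibble: quadrant,
#'   slope ms/index), `frequency` (Hz), `period` (ms),
#'   `dorsoventral_phase` and `left_right_phase` (fractions of a period in
#'   \[0, 1)).
#' @export
wave_metrics <- function(result, muscle_order = NULL, settle_time = 0,
                         prom_frac = 0.5, min_peak_dist = 50) {
  if (inherits(result, "simulation_result")) {
    if (is.null(result$Ca)) stop("simulation result has no calcium traces")
    tt <- result$times
    traces <- t(result$Ca)
  } else {
    result <- as.data.frame(result)
    if (!"time" %in% names(result)) stop("data frame input needs a 'time' column")
    tt <- result$time
    traces <- as.matrix(result[setdiff(names(result), "time")])
  }
  if (settle_time >= max(tt)) stop("settle_time must be shorter than the recording")
  if (is.null(muscle_order)) {
    muscle_order <- purrr::map(locomotion_muscle_order(),
                               ~ intersect(.x, colnames(traces)))
    muscle_order <- muscle_order[lengths(muscle_order) > 0]
    if (length(muscle_order) == 0) {
      muscle_order <- list(all = colnames(traces))
    }
  }
  keep <- tt >= settle_time
  tt <- tt[keep]

  peak_list <- list()
  for (q in names(muscle_order)) {
    for (i in seq_along(muscle_order[[q]])) {
      m <- muscle_order[[q]][i]
      if (!m %in% colnames(traces)) stop("no trace recorded for muscle ", m)
      pk <- find_ca_peaks(tt, traces[keep, m], prom_frac, min_peak_dist)
      if (length(pk) == 0) stop("no calcium peaks found for muscle ", m)
      peak_list[[length(peak_list) + 1]] <- tibble::tibble(
        muscle = m, quadrant = q, index = i,
        first_peak = pk[1], n_peaks = length(pk),
        peak_times = list(pk))
    }
  }
  peaks <- dplyr::bind_rows(peak_list)

  slopes <- peaks |>
    dplyr::group_by(.data$quadrant) |>
    dplyr::summarise(slope = if (dplyr::n() >= 2)
      stats::coef(stats::lm(first_peak ~ index))[["index"]] else NA_real_,
      .groups = "drop")

  # frequency from the first muscle (of the first quadrant) with >= 2 peaks
  all_pk <- peaks$peak_times[order(peaks$quadrant != names(muscle_order)[1],
                                   peaks$index)]
  ref <- purrr::detect(all_pk, ~ length(.x) >= 2)
  if (is.null(ref)) stop("no muscle shows repeated calcium peaks; cannot estimate frequency")
  period <- stats::median(diff(ref))
  frequency <- 1000 / period

  phase_between <- function(q1, q2) {
    a <- peaks[peaks$quadrant == q1, c("index", "first_peak")]
    b <- peaks[peaks$quadrant == q2, c("index", "first_peak")]
    j <- dplyr::inner_join(a, b, by = "index", suffix = c("_a", "_b"))
    if (nrow(j) == 0) return(NA_real_)
    circular_mean_phase(j$first_peak_b - j$first_peak_a, period)
  }
  quadnames <- names(muscle_order)
  dv <- if (all(c("MDL", "MVL") %in% quadnames)) {
    dts <- c()
    for (pair in list(c("MDL", "MVL"), c("MDR", "MVR"))) {
      if (all(pair %in% quadnames)) dts <- c(dts, phase_between(pair[1], pair[2]))
    }
    circular_mean_phase(dts * period, period)
  } else NA_real_
  lr <- if (all(c("MDL", "MDR") %in% quadnames)) phase_between("MDL", "MDR") else NA_real_

  structure(list(peaks = peaks, slopes = slopes, frequency = frequency,
                 period = period, dorsoventral_phase = dv,
                 left_right_phase = lr, settle_time = settle_time),
            class = "wave_metrics")
}

#' @export
print.wave_metrics <- function(x, ...) {
  cat("<wave_metrics>", nrow(x$peaks), "muscles analysed\n")
  cat(sprintf("  frequency: %.3f Hz (period %.1f ms)\n", x$frequency, x$period))
  for (i in seq_len(nrow(x$slopes))) {
    cat(sprintf("  %s propagation slope: %.2f ms/muscle\n",
                x$slopes$quadrant[i], x$slopes$slope[i]))
  }
  cat(sprintf("  dorsoventral phase: %.3f  left-right phase: %.3f (of a period)\n",
              x$dorsoventral_phase, x$left_right_phase))
  invisible(x)
}

#' @export
tidy.wave_metrics <- function(x, ...) {
  dplyr::select(x$peaks, "muscle", "quadrant", "index", "first_peak", "n_peaks")
}

#' @export
glance.wave_metrics <- function(x, ...) {
  sl <- stats::setNames(x$slopes$slope, paste0("slope_", x$slopes$quadrant))
  dplyr::bind_cols(
    tibble::tibble(frequency = x$frequency, period = x$period,
                   dorsoventral_phase = x$dorsoventral_phase,
                   left_right_phase = x$left_right_phase),
    tibble::as_tibble(as.list(sl)))
}

#' Plot the travelling wave: first-peak time against body position
#'
#' @param object A `wave_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wave_metrics <- function(object, ...) {
  ggplot2::ggplot(object$peaks,
                  ggplot2::aes(x = .data$index, y = .data$first_peak,
                               colour = .data$quadrant)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "muscle index (anterior to posterior)",
                  y = "first calcium peak (ms)", colour = "quadrant") +
    ggplot2::theme_minimal()
}

#' Build, couple, simulate and analyse the forward-locomotion circuit
#'
#' Convenience pipeline: builds the circuit, adds the proprioceptive
#' coupling, runs the simulator and computes the travelling-wave metrics
#' from the muscle calcium traces.
#'
#' @param params A `parameter_set`, level C or C1.
#' @param cfg A [locomotion_config()].
#' @param duration Simulated time, ms.
#' @param dt Time step, ms.
#' @param record_every Recording stride in steps.
#' @param settle_time Settling period excluded from the wave analysis, ms;
#'   defaults to one CPG period.
#' @return List with `network`, `result` and `metrics`.
#' @export
run_forward_locomotion <- function(params = default_parameters("C1"),
                                   cfg = locomotion_config(),
                                   duration = 5000, dt = 0.05,
                                   record_every = 10,
                                   settle_time = cfg$cpg_period) {
  net <- build_forward_locomotion(params, cfg)
  net <- add_proprioceptive_coupling(net, cfg$proprio_gain)
  res <- simulate_network(net, duration = duration, dt = dt,
                          record_every = record_every)
  metrics <- wave_metrics(res, settle_time = settle_time)
  list(network = net, result = res, metrics = metrics)
}
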