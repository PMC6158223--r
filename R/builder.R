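#' Body-wall muscle layout
#'
#' The 96 body-wall muscles are organised into four quadrants (dorsal/ventral
#' x left/right) of 24 muscles each, named `MDL01`-`MDL24`, `MDR01`-`MDR24`,
#' `MVL01`-`MVL24`, `MVR01`-`MVR24`. They are laid out as four parallel rows
#' offset from the body axis, ordered anterior to posterior by index, which
#' makes connection and activity displays legible.
#'
#' @return Tibble with columns `name`, `quadrant`, `index`, `x`, `y`, `z`
#'   (micrometres; `x` is the anterior-posterior axis).
#' @export
layout_muscles <- function() {
  quadrants <- tibble::tibble(
    quadrant = c("MDL", "MDR", "MVL", "MVR"),
    y = c(20, 20, -20, -20),
    z = c(-20, 20, -20, 20))
  tidyr::crossing(quadrants, index = 1:24) |>
    dplyr::mutate(name = sprintf("%s%02d", .data$quadrant, .data$index),
                  x = 40 * .data$index) |>
    dplyr::select("name", "quadrant", "index", "x", "y", "z") |>
    dplyr::arrange(.data$quadrant, .data$index)
}

new_network_model <- function(cells, synapses, stimuli, params) {
  structure(list(cells = tibble::as_tibble(cells),
                 synapses = tibble::as_tibble(synapses),
                 stimuli = tibble::as_tibble(stimuli),
                 params = params),
            class = "network_model")
}

empty_synapses <- function() {
  tibble::tibble(pre = character(), post = character(),
                 kind = character(), weight = double())
}

empty_stimuli <- function() {
  tibble::tibble(target = character(), amplitude = double(), onset = double(),
                 pulse_duration = double(), period = double(), n_pulses = double())
}

#' Instantiate an executable network from a connectome and a parameter set
#'
#' Each selected cell becomes one model instance (muscles get the muscle cell
#' parameters, everything else the neuron parameters) at its soma position.
#' Each chemical connection becomes one synapse with weight
#' `baseline_chem * n_contacts` and kind `chem_inh` when the presynaptic
#' neurotransmitter is GABA, `chem_exc` otherwise; each gap junction becomes
#' one symmetric `gap` synapse with weight `baseline_gap * n_contacts`.
#' At detail level A gap junctions are instead converted into a pair of
#' directed spike-triggered excitatory synapses of equal weight.
#'
#' @param x A [connectome].
#' @param params A `parameter_set` (see [default_parameters()]).
#' @param subset Character vector of cell names to keep, or `NULL` for all.
#' @return A `network_model`.
#' @export
build_network <- function(x, params, subset = NULL) {
  params <- validate_parameter_set(unclass(params))
  if (!is.null(subset)) x <- subset_connectome(x, subset)
  cells <- dplyr::mutate(x$cells,
    model_group = ifelse(.data$cell_class == "muscle", "muscle", "neuron"))

  chem <- x$chemical
  if (nrow(chem) > 0) {
    # Per-row neurotransmitter, falling back to the presynaptic cell's
    # annotation when the row itself is unannotated.
    cell_nt <- stats::setNames(x$cells$neurotransmitter, x$cells$name)
    nt <- ifelse(chem$neurotransmitter == "UNKNOWN",
                 unname(cell_nt[chem$pre]), chem$neurotransmitter)
    chem_syn <- tibble::tibble(
      pre = chem$pre, post = chem$post,
      kind = ifelse(classify_polarity(nt) == "inhibitory", "chem_inh", "chem_exc"),
      weight = connection_weight(chem$n_contacts, params$baseline_chem))
  } else {
    chem_syn <- empty_synapses()
  }

  elec <- x$electrical
  if (nrow(elec) > 0) {
    w <- connection_weight(elec$n_contacts, params$baseline_gap)
    if (isTRUE(params$gap$as_spike_synapse)) {
      gap_syn <- tibble::tibble(
        pre = c(elec$cell_a, elec$cell_b), post = c(elec$cell_b, elec$cell_a),
        kind = "chem_exc", weight = c(w, w))
    } else {
      gap_syn <- tibble::tibble(pre = elec$cell_a, post = elec$cell_b,
                                kind = "gap", weight = w)
    }
  } else {
    gap_syn <- empty_synapses()
  }

  new_network_model(cells, dplyr::bind_rows(chem_syn, gap_syn),
                    empty_stimuli(), params)
}

#' Attach a current-injection stimulus protocol to a cell
#'
#' A protocol is a square current pulse of the given amplitude and duration,
#' optionally repeated with a fixed period for a given number of pulses
#' (`n_pulses = Inf` repeats for the whole simulation; `period = NA` gives a
#' single pulse).
#'
#' @param net A `network_model`.
#' @param target Cell name.
#' @param amplitude Current, pA.
#' @param onset Start of the first pulse, ms.
#' @param pulse_duration Pulse width, ms.
#' @param period Pulse period, ms, or `NA` for a single pulse.
#' @param n_pulses Number of pulses (`Inf` = unbounded).
#' @return The network with the protocol appended.
#' @export
add_stimulus <- function(net, target, amplitude, onset = 0,
                         pulse_duration = Inf, period = NA_real_,
                         n_pulses = Inf) {
  if (!target %in% net$cells$name) stop("unknown stimulus target: ", target)
  if (!is.na(period) && pulse_duration > period) {
    stop("pulse_duration must not exceed period")
  }
  if (!is.finite(amplitude)) stop("stimulus amplitude must be finite")
  net$stimuli <- dplyr::bind_rows(net$stimuli, tibble::tibble(
    target = target, amplitude = amplitude, onset = onset,
    pulse_duration = pulse_duration, period = period, n_pulses = n_pulses))
  net
}

#' Override the weight of one synapse
#'
#' Connection weights default to baseline x contact count; individual
#' connections can be modified to probe how weight changes affect network
#' behaviour. Exactly the named synapse changes.
#'
#' @param net A `network_model`.
#' @param pre,post Cell names of the synapse endpoints.
#' @param kind `"chem_exc"`, `"chem_inh"` or `"gap"`.
#' @param new_weight New weight, nS.
#' @return The modified network.
#' @export
override_weight <- function(net, pre, post, kind, new_weight) {
  hit <- which(net$synapses$pre == pre & net$synapses$post == post &
               net$synapses$kind == kind)
  if (length(hit) == 0) {
    stop("no ", kind, " synapse from ", pre, " to ", post)
  }
  net$synapses$weight[hit] <- new_weight
  net
}

#' Four-pair demonstration network
#'
#' Eight single-compartment cells: four presynaptic neurons, each receiving
#' two pulses of injected current, coupled one-to-one to four targets by the
#' four connection classes — excitatory chemical synapse, inhibitory chemical
#' synapse, gap junction, and excitatory chemical synapse onto a muscle cell.
#' Simulated at a conductance-based level, the excitatory targets
#' depolarise, the inhibitory target hyperpolarises below rest, and the
#' gap-coupled target follows its partner.
#'
#' @param params A `parameter_set`.
#' @param n_contacts Contact count used for every demo connection (the weight
#'   follows the usual baseline x contacts rule). The default of 50 makes the
#'   postsynaptic responses clearly visible at the default baselines.
#' @param stim_amplitude,stim_duration,stim_period Stimulus pulse parameters
#'   (two pulses per presynaptic cell).
#' @return A `network_model`.
#' @export
build_four_pair_demo <- function(params = default_parameters("C"),
                                 n_contacts = 50, stim_amplitude = 20,
                                 stim_duration = 100, stim_period = 250) {
  neurons <- c("PRE_EXC", "POST_EXC", "PRE_INH", "POST_INH",
               "PRE_GAP", "POST_GAP", "PRE_MUS")
  cells <- tibble::tibble(
    name = c(neurons, "MDL01"),
    cell_class = c(rep("interneuron", 7), "muscle"),
    neurotransmitter = c("Acetylcholine", "UNKNOWN", "GABA", "UNKNOWN",
                         "UNKNOWN", "UNKNOWN", "Acetylcholine", "UNKNOWN"))
  cells <- dplyr::bind_cols(cells, default_positions(cells))
  cx <- connectome(
    cells = cells,
    chemical = tibble::tibble(
      pre = c("PRE_EXC", "PRE_INH", "PRE_MUS"),
      post = c("POST_EXC", "POST_INH", "MDL01"),
      n_contacts = rep(as.integer(n_contacts), 3),
      neurotransmitter = c("Acetylcholine", "GABA", "Acetylcholine")),
    electrical = tibble::tibble(cell_a = "POST_GAP", cell_b = "PRE_GAP",
                                n_contacts = as.integer(n_contacts)),
    source_tag = "four_pair_demo")
  net <- build_network(cx, params)
  for (pre in c("PRE_EXC", "PRE_INH", "PRE_GAP", "PRE_MUS")) {
    net <- add_stimulus(net, pre, amplitude = stim_amplitude, onset = 50,
                        pulse_duration = stim_duration, period = stim_period,
                        n_pulses = 2)
  }
  net
}

#' @export
print.network_model <- function(x, ...) {
  counts <- table(factor(x$synapses$kind, levels = c("chem_exc", "chem_inh", "gap")))
  cat("<network_model> level", x$params$level, "\n")
  cat("  cells:   ", nrow(x$cells), sprintf("(%d neurons, %d muscles)",
      sum(x$cells$model_group == "neuron"), sum(x$cells$model_group == "muscle")), "\n")
  cat("  synapses:", nrow(x$synapses),
      sprintf("(%d exc, %d inh, %d gap)", counts[["chem_exc"]],
              counts[["chem_inh"]], counts[["gap"]]), "\n")
  cat("  stimuli: ", nrow(x$stimuli), "\n")
  invisible(x)
}

#' @export
tidy.network_model <- function(x, ...) x$synapses

#' @export
glance.network_model <- function(x, ...) {
  tibble::tibble(
    level = x$params$level,
    n_cells = nrow(x$cells),
    n_neurons = sum(x$cells$model_group == "neuron"),
    n_muscles = sum(x$cells$model_group == "muscle"),
    n_synapses = nrow(x$synapses),
    n_gap = sum(x$synapses$kind == "gap"),
    n_stimuli = nrow(x$stimuli),
    total_chem_weight = sum(x$synapses$weight[x$synapses$kind != "gap"]))
}
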