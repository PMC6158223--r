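#' Load a shipped parameter set
#'
#' Parameter sets fix every constant needed to turn a wiring diagram into an
#' executable model, at one of four levels of biophysical detail:
#'
#' * `A` — leaky integrate-and-fire (LIF) cells; spike-triggered synaptic
#'   transmission for every connection, including the gap-junction entries
#'   (converted to excitatory spike synapses of equal weight).
#' * `B` — LIF cells plus a low-pass "activity" variable (a firing-rate
#'   proxy, recorded but not fed back onto the dynamics); true electrical
#'   gap junctions.
#' * `C` — single-compartment conductance-based cells with voltage-gated
#'   channels and an intracellular calcium pool; spike-triggered chemical
#'   synapses and gap junctions.
#' * `C1` — as `C` but chemical transmission is through continuously
#'   transmitting graded (analogue) synapses, the better approximation for
#'   the mostly non-spiking C. elegans nervous system.
#'
#' All constants are in the package unit system: mV, ms, nS, pA, pF, uM
#' (self-consistent: nS x mV = pA; pA / pF = mV / ms).
#'
#' @param level `"A"`, `"B"`, `"C"` or `"C1"`.
#' @param file Optional path to a parameter JSON document to load instead of
#'   the shipped one (its `level` field still selects the model families).
#' @return A `parameter_set` object (a validated named list).
#' @export
#' @examples
#' p <- default_parameters("C1")
#' p$baseline_chem
default_parameters <- function(level = c("A", "B", "C", "C1"), file = NULL) {
  if (is.null(file)) {
    level <- match.arg(level)
    file <- system.file("extdata", "parameters",
                        sprintf("parameters_%s.json", level),
                        package = "wormcircuit", mustWork = TRUE)
  }
  p <- jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  validate_parameter_set(p)
}

#' Validate a parameter set
#'
#' Checks the invariants of every constant block (positive capacitances and
#' time constants, non-negative conductances, reset below threshold, gate
#' exponents at least 1) and that the synapse kinds match the level: spike
#' synapses at A/B/C, graded synapses at C1.
#'
#' @param p A named list as produced by [default_parameters()].
#' @return `p` with class `parameter_set`, or an error.
#' @export
validate_parameter_set <- function(p) {
  stopifnot(is.list(p))
  if (!p$level %in% c("A", "B", "C", "C1")) {
    stop("unknown parameter level tag: ", p$level)
  }
  for (cell in c("neuron_params", "muscle_params")) {
    cp <- p[[cell]]
    if (is.null(cp)) stop("missing ", cell)
    if (cp$C_m <= 0) stop(cell, ": C_m must be > 0")
    if (cp$g_leak < 0) stop(cell, ": g_leak must be >= 0")
    if (identical(cp$model, "lif")) {
      if (cp$V_reset > cp$V_thresh) stop(cell, ": V_reset must be <= V_thresh")
      if (cp$t_refract < 0) stop(cell, ": t_refract must be >= 0")
    } else if (identical(cp$model, "conductance")) {
      if (cp$ca_tau <= 0) stop(cell, ": ca_tau must be > 0")
      if (cp$ca_rho < 0) stop(cell, ": ca_rho must be >= 0")
      for (ch in cp$channels) {
        if (ch$gbar < 0) stop(cell, ": channel gbar must be >= 0")
        validate_gate(ch$activation, cell)
        if (!is.null(ch$inactivation)) validate_gate(ch$inactivation, cell)
      }
    } else {
      stop(cell, ": unknown cell model '", cp$model, "'")
    }
  }
  expected_kind <- if (p$level == "C1") "graded" else "spike"
  for (syn in c("exc_syn", "inh_syn")) {
    sp <- p[[syn]]
    if (!identical(sp$kind, expected_kind)) {
      stop(syn, ": level ", p$level, " requires ", expected_kind, " synapses")
    }
    if (sp$kind == "spike" && sp$tau_decay <= 0) stop(syn, ": tau_decay must be > 0")
    if (sp$kind == "graded") {
      if (sp$tau_s <= 0) stop(syn, ": tau_s must be > 0")
      if (sp$delta == 0) stop(syn, ": delta must be non-zero")
    }
  }
  if (p$level == "A" && !isTRUE(p$gap$as_spike_synapse)) {
    stop("level A maps gap-junction entries onto spike synapses (gap$as_spike_synapse)")
  }
  if (p$level != "A" && isTRUE(p$gap$as_spike_synapse)) {
    stop("levels B/C/C1 use true electrical gap junctions")
  }
  if (p$baseline_chem < 0 || p$baseline_gap < 0) stop("baselines must be >= 0")
  if (p$level == "B" && is.null(p$activity)) stop("level B requires an activity block")
  structure(p, class = "parameter_set")
}

validate_gate <- function(g, where) {
  if (g$tau <= 0) stop(where, ": gate tau must be > 0")
  if (g$exponent < 1 || g$exponent != round(g$exponent)) {
    stop(where, ": gate exponent must be a positive integer")
  }
  invisible(g)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> level", x$level, "\n")
  cat(" ", x$description, "\n")
  cat("  neurons:", x$neuron_params$model,
      "| muscles:", x$muscle_params$model,
      "| synapses:", x$exc_syn$kind, "\n")
  cat("  baseline conductance per contact:", x$baseline_chem,
      "nS (chemical),", x$baseline_gap, "nS (gap)\n")
  invisible(x)
}
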