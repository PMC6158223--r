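#' Dump a network model as JSON
#'
#' A machine-readable description of the instantiated network — cells (with
#' positions and model level), synapses (pre, post, kind, weight) and
#' stimulus protocols — with stable key order so dumps of identical networks
#' diff cleanly.
#'
#' @param net A `network_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_network_json <- function(net, file) {
  doc <- list(
    level = net$params$level,
    baseline_chem = net$params$baseline_chem,
    baseline_gap = net$params$baseline_gap,
    cells = net$cells[, c("name", "cell_class", "neurotransmitter",
                          "model_group", "x", "y", "z")],
    synapses = net$synapses[, c("pre", "post", "kind", "weight")],
    stimuli = net$stimuli)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(file)
}

neuroml_ns <- "http://www.neuroml.org/schema/neuroml2"

#' Export a network in a NeuroML-style XML subset
#'
#' Writes the structural elements of the network in the NeuroML v2 namespace:
#' one `network` element containing `population` elements per cell group
#' (with per-instance `location` children and the cell name carried in a
#' `property` child), `projection` elements with `connectionWD` children for
#' spike-triggered chemical synapses — or `continuousProjection` /
#' `continuousConnectionInstanceW` when the parameter level uses graded
#' synapses — `electricalProjection` elements for gap junctions, and
#' `explicitInput` elements per stimulus referencing `pulseGenerator`
#' definitions. This subset captures the structure (cells, positions,
#' connectivity, weights, inputs); the built-in simulator is the executable
#' semantics.
#'
#' @param net A `network_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_neuroml_subset <- function(net, file) {
  doc <- xml2::xml_new_root("neuroml", xmlns = neuroml_ns, id = "wormcircuit_network")
  cells <- net$cells
  groups <- split(seq_len(nrow(cells)), cells$model_group)
  groups <- groups[order(names(groups))]

  # stimulus waveform definitions
  st <- net$stimuli
  if (nrow(st) > 0) {
    for (i in seq_len(nrow(st))) {
      pg <- xml2::xml_add_child(doc, "pulseGenerator",
        id = sprintf("stim_%d", i),
        delay = sprintf("%gms", st$onset[i]),
        duration = sprintf("%gms", st$pulse_duration[i]),
        amplitude = sprintf("%gpA", st$amplitude[i]))
      if (!is.na(st$period[i])) xml2::xml_set_attr(pg, "period", sprintf("%gms", st$period[i]))
      if (is.finite(st$n_pulses[i])) xml2::xml_set_attr(pg, "number", st$n_pulses[i])
    }
  }

  network <- xml2::xml_add_child(doc, "network", id = "network")
  cell_ref <- character(nrow(cells))  # "pop_id/index" per cell
  for (g in names(groups)) {
    idx <- groups[[g]]
    pop <- xml2::xml_add_child(network, "population",
      id = paste0("pop_", g), component = paste0(g, "_", net$params$level),
      size = length(idx), type = "populationList")
    for (j in seq_along(idx)) {
      ci <- idx[j]
      inst <- xml2::xml_add_child(pop, "instance", id = j - 1)
      xml2::xml_add_child(inst, "property", tag = "name", value = cells$name[ci])
      xml2::xml_add_child(inst, "location",
                          x = cells$x[ci], y = cells$y[ci], z = cells$z[ci])
      cell_ref[ci] <- sprintf("../pop_%s/%d", g, j - 1)
    }
  }
  names(cell_ref) <- cells$name

  syn <- net$synapses
  graded <- net$params$exc_syn$kind == "graded"
  add_proj <- function(kind, syn_id) {
    rows <- which(syn$kind == kind)
    if (length(rows) == 0) return(invisible())
    if (kind == "gap") {
      proj <- xml2::xml_add_child(network, "electricalProjection",
        id = "proj_gap", presynapticPopulation = "pop_all",
        postsynapticPopulation = "pop_all")
      for (k in seq_along(rows)) {
        r <- rows[k]
        xml2::xml_add_child(proj, "electricalConnectionInstanceW",
          id = k - 1, preCell = cell_ref[[syn$pre[r]]],
          postCell = cell_ref[[syn$post[r]]],
          synapse = "gap_junction", weight = syn$weight[r])
      }
    } else if (graded) {
      proj <- xml2::xml_add_child(network, "continuousProjection",
        id = paste0("proj_", kind), presynapticPopulation = "pop_all",
        postsynapticPopulation = "pop_all")
      for (k in seq_along(rows)) {
        r <- rows[k]
        xml2::xml_add_child(proj, "continuousConnectionInstanceW",
          id = k - 1, preCell = cell_ref[[syn$pre[r]]],
          postCell = cell_ref[[syn$post[r]]],
          preComponent = "silentSynapse", postComponent = syn_id,
          weight = syn$weight[r])
      }
    } else {
      proj <- xml2::xml_add_child(network, "projection",
        id = paste0("proj_", kind), presynapticPopulation = "pop_all",
        postsynapticPopulation = "pop_all", synapse = syn_id)
      for (k in seq_along(rows)) {
        r <- rows[k]
        xml2::xml_add_child(proj, "connectionWD",
          id = k - 1, preCellId = cell_ref[[syn$pre[r]]],
          postCellId = cell_ref[[syn$post[r]]],
          weight = syn$weight[r], delay = "0ms")
      }
    }
  }
  add_proj("chem_exc", "exc_syn")
  add_proj("chem_inh", "inh_syn")
  add_proj("gap", "gap_junction")

  if (nrow(st) > 0) {
    for (i in seq_len(nrow(st))) {
      xml2::xml_add_child(network, "explicitInput",
        target = cell_ref[[st$target[i]]], input = sprintf("stim_%d", i))
    }
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

#' Re-parse the structural content of a NeuroML-subset export
#'
#' Recovers the cell list (names, groups, positions) and the synapse table
#' (pre, post, kind, weight) from a document written by
#' [write_neuroml_subset()], for structural round-trip checks.
#'
#' @param file Path to the XML document.
#' @return List with `cells` and `synapses` tibbles.
#' @export
read_neuroml_network <- function(file) {
  doc <- xml2::read_xml(file)
  ns <- c(n = neuroml_ns)
  insts <- xml2::xml_find_all(doc, ".//n:population/n:instance", ns)
  pops <- vapply(seq_along(insts), function(i)
    xml2::xml_attr(xml2::xml_parent(insts[[i]]), "id"), character(1))
  cells <- tibble::tibble(
    name = xml2::xml_attr(xml2::xml_find_first(insts, "./n:property", ns), "value"),
    group = sub("^pop_", "", pops),
    index = as.integer(xml2::xml_attr(insts, "id")),
    x = as.numeric(xml2::xml_attr(xml2::xml_find_first(insts, "./n:location", ns), "x")),
    y = as.numeric(xml2::xml_attr(xml2::xml_find_first(insts, "./n:location", ns), "y")),
    z = as.numeric(xml2::xml_attr(xml2::xml_find_first(insts, "./n:location", ns), "z")))
  ref_to_name <- stats::setNames(cells$name,
                                 sprintf("../pop_%s/%d", cells$group, cells$index))

  conns <- xml2::xml_find_all(doc, paste0(
    ".//n:connectionWD | .//n:continuousConnectionInstanceW",
    " | .//n:electricalConnectionInstanceW"), ns)
  if (length(conns) > 0) {
    proj_id <- vapply(seq_along(conns), function(i)
      xml2::xml_attr(xml2::xml_parent(conns[[i]]), "id"), character(1))
    pre <- xml2::xml_attr(conns, "preCellId")
    pre2 <- xml2::xml_attr(conns, "preCell")
    pre[is.na(pre)] <- pre2[is.na(pre)]
    post <- xml2::xml_attr(conns, "postCellId")
    post2 <- xml2::xml_attr(conns, "postCell")
    post[is.na(post)] <- post2[is.na(post)]
    synapses <- tibble::tibble(
      pre = unname(ref_to_name[pre]), post = unname(ref_to_name[post]),
      kind = sub("^proj_", "", proj_id),
      weight = as.numeric(xml2::xml_attr(conns, "weight")))
  } else {
    synapses <- empty_synapses()
  }
  list(cells = cells[, c("name", "group", "x", "y", "z")], synapses = synapses)
}

#' Write recorded traces as a wide CSV
#'
#' One row per sample: a `time` column plus one column per recorded trace,
#' headed `cellname.v` (membrane potential, mV) and `cellname.ca`
#' (calcium, uM).
#'
#' @param result A `simulation_result`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_results_csv <- function(result, file) {
  out <- tibble::tibble(time = result$times)
  if (!is.null(result$V)) {
    v <- tibble::as_tibble(t(result$V))
    names(v) <- paste0(rownames(result$V), ".v")
    out <- dplyr::bind_cols(out, v)
  }
  if (!is.null(result$Ca)) {
    ca <- tibble::as_tibble(t(result$Ca))
    names(ca) <- paste0(rownames(result$Ca), ".ca")
    out <- dplyr::bind_cols(out, ca)
  }
  readr::write_csv(out, file, progress = FALSE)
  invisible(file)
}

#' Write spike times as a two-column CSV (`cell`, `time`)
#'
#' @param result A `simulation_result` with spikes recorded.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_spikes_csv <- function(result, file) {
  if (is.null(result$spikes)) stop("no spikes recorded")
  df <- tibble::tibble(
    cell = rep(names(result$spikes), lengths(result$spikes)),
    time = unlist(result$spikes, use.names = FALSE))
  readr::write_csv(df, file, progress = FALSE)
  invisible(file)
}

#' Write a cells x time matrix for heatmap displays
#'
#' @param result A `simulation_result`.
#' @param file Output path.
#' @param variable `"v"` or `"ca"`.
#' @return `file`, invisibly.
#' @export
write_heatmap_matrix <- function(result, file, variable = c("v", "ca")) {
  variable <- match.arg(variable)
  m <- if (variable == "v") result$V else result$Ca
  if (is.null(m)) stop("variable '", variable, "' was not recorded")
  df <- dplyr::bind_cols(tibble::tibble(cell = rownames(m)),
                         tibble::as_tibble(m, .name_repair = ~ sprintf("t%g", result$times)))
  readr::write_csv(df, file, progress = FALSE)
  invisible(file)
}

#' Read a results CSV back into a trace table
#'
#' Inverse of [write_results_csv()] for analysis pipelines: returns a tibble
#' with the `time` column and one column per trace; `variable` selects the
#' membrane-potential (`.v`) or calcium (`.ca`) columns, renamed to bare
#' cell names.
#'
#' @param file Path to the CSV.
#' @param variable `"ca"` or `"v"`.
#' @return A tibble.
#' @export
read_results_csv <- function(file, variable = c("ca", "v")) {
  variable <- match.arg(variable)
  x <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  suffix <- paste0(".", variable)
  keep <- c("time", names(x)[endsWith(names(x), suffix)])
  out <- x[keep]
  names(out) <- sub(paste0("\\Q", suffix, "\\E$"), "", names(out))
  out
}
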