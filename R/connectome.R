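#' Construct a connectome object
#'
#' A connectome bundles the identified cells of a wiring diagram together with
#' its chemical synaptic connections (directed, with anatomical contact counts
#' and a neurotransmitter annotation) and its gap-junction connections
#' (undirected, with contact counts).
#'
#' @param cells Tibble with columns `name`, `cell_class` (one of `"sensory"`,
#'   `"interneuron"`, `"motorneuron"`, `"muscle"`), `neurotransmitter`
#'   (`"UNKNOWN"` when not annotated) and soma coordinates `x`, `y`, `z`
#'   in micrometres.
#' @param chemical Tibble with columns `pre`, `post`, `n_contacts`,
#'   `neurotransmitter`.
#' @param electrical Tibble with columns `cell_a`, `cell_b`, `n_contacts`.
#'   Pairs are unordered; each pair is stored once with `cell_a < cell_b`.
#' @param source_tag Character scalar recording where the wiring came from.
#'
#' @return An object of class `connectome`.
#' @export
connectome <- function(cells = empty_cells(), chemical = empty_chemical(),
                       electrical = empty_electrical(), source_tag = "manual") {
  cells <- tibble::as_tibble(cells)
  chemical <- tibble::as_tibble(chemical)
  electrical <- tibble::as_tibble(electrical)
  if (anyDuplicated(cells$name)) {
    stop("duplicate cell names: ",
         paste(unique(cells$name[duplicated(cells$name)]), collapse = ", "))
  }
  if (any(!is.finite(as.matrix(cells[, c("x", "y", "z")])) )) {
    stop("non-finite soma position")
  }
  endpoints <- c(chemical$pre, chemical$post, electrical$cell_a, electrical$cell_b)
  unknown <- setdiff(endpoints, cells$name)
  if (length(unknown) > 0) {
    stop("connection endpoints not registered as cells: ",
         paste(sort(unique(unknown)), collapse = ", "))
  }
  if (nrow(chemical) > 0 && any(chemical$n_contacts < 1)) stop("chemical n_contacts must be >= 1")
  if (nrow(electrical) > 0 && any(electrical$n_contacts < 1)) stop("electrical n_contacts must be >= 1")
  structure(list(cells = cells, chemical = chemical, electrical = electrical,
                 source_tag = source_tag),
            class = "connectome")
}

empty_cells <- function() {
  tibble::tibble(name = character(), cell_class = character(),
                 neurotransmitter = character(),
                 x = double(), y = double(), z = double())
}

empty_chemical <- function() {
  tibble::tibble(pre = character(), post = character(),
                 n_contacts = integer(), neurotransmitter = character())
}

empty_electrical <- function() {
  tibble::tibble(cell_a = character(), cell_b = character(), n_contacts = integer())
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> source:", x$source_tag, "\n")
  cat("  cells:     ", nrow(x$cells), "\n")
  cat("  chemical:  ", nrow(x$chemical), "connections,",
      sum(x$chemical$n_contacts), "contacts\n")
  cat("  electrical:", nrow(x$electrical), "gap-junction pairs,",
      sum(x$electrical$n_contacts), "contacts\n")
  invisible(x)
}

#' Tidy a connectome into one edge table
#'
#' Returns one row per connection with a `type` column (`"chemical"` or
#' `"electrical"`). Electrical pairs appear once, in their stored
#' (alphabetical) orientation.
#'
#' @param x A [connectome].
#' @param ... Unused.
#' @return A tibble with columns `pre`, `post`, `type`, `n_contacts`,
#'   `neurotransmitter`, `polarity`.
#' @export
tidy.connectome <- function(x, ...) {
  chem <- dplyr::mutate(x$chemical, type = "chemical",
                        polarity = classify_polarity(.data$neurotransmitter))
  elec <- tibble::tibble(pre = x$electrical$cell_a, post = x$electrical$cell_b,
                         n_contacts = x$electrical$n_contacts,
                         neurotransmitter = NA_character_,
                         type = "electrical", polarity = NA_character_)
  dplyr::bind_rows(chem, elec)[, c("pre", "post", "type", "n_contacts",
                                   "neurotransmitter", "polarity")]
}

#' @export
glance.connectome <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_chemical = nrow(x$chemical),
    n_electrical = nrow(x$electrical),
    total_contacts = sum(x$chemical$n_contacts) + sum(x$electrical$n_contacts),
    gaba_fraction = if (nrow(x$chemical) > 0)
      mean(classify_polarity(x$chemical$neurotransmitter) == "inhibitory") else NA_real_,
    source_tag = x$source_tag
  )
}

# Canonical title-casing of a neurotransmitter token; blank -> UNKNOWN.
normalise_transmitter <- function(nt) {
  nt <- trimws(as.character(nt))
  nt[is.na(nt) | nt == ""] <- "UNKNOWN"
  gaba <- toupper(nt) == "GABA"
  unknown <- nt == "UNKNOWN"
  out <- paste0(toupper(substring(nt, 1, 1)), tolower(substring(nt, 2)))
  out[gaba] <- "GABA"
  out[unknown] <- "UNKNOWN"
  out
}

#' Classify synaptic polarity from the presynaptic neurotransmitter
#'
#' A connection is inhibitory exactly when the presynaptic cell transmits GABA
#' (case-insensitive); every other annotation, including `"UNKNOWN"`, is
#' treated as excitatory. This first-approximation rule mirrors how polarity
#' is assigned in connectome-wide models where per-synapse receptor data are
#' unavailable.
#'
#' @param neurotransmitter Character vector of neurotransmitter names.
#' @return Character vector, `"excitatory"` or `"inhibitory"`.
#' @export
#' @examples
#' classify_polarity(c("GABA", "Acetylcholine", "UNKNOWN"))
classify_polarity <- function(neurotransmitter) {
  ifelse(toupper(trimws(neurotransmitter)) == "GABA", "inhibitory", "excitatory")
}

#' Synaptic weight from contact count
#'
#' The conductance assigned to a cell pair is the product of a per-contact
#' baseline conductance and the number of anatomical contacts between the
#' pair, so e.g. 13 contacts at a 0.01 nS baseline yield 0.13 nS.
#'
#' @param n_contacts Positive integer vector of anatomical contact counts.
#' @param baseline_conductance Baseline conductance per contact, nS (>= 0).
#' @return Conductance in nS.
#' @export
#' @examples
#' connection_weight(13, 0.01)
connection_weight <- function(n_contacts, baseline_conductance) {
  if (any(baseline_conductance < 0)) stop("baseline_conductance must be >= 0")
  if (any(n_contacts < 1) || any(n_contacts != round(n_contacts))) {
    stop("n_contacts must be a positive integer")
  }
  n_contacts * baseline_conductance
}

# ---------------------------------------------------------------------------
# Readers / writers

varshney_chem_types <- c("S", "Sp", "NMJ")
varshney_skip_types <- c("R", "Rp")

dialect_spec <- function(dialect) {
  switch(dialect,
    varshney = list(
      pre = "Neuron 1", post = "Neuron 2", type = "Type", n = "Nbr",
      nt = NULL,
      is_gap = function(type) type == "EJ",
      is_chem = function(type) type %in% varshney_chem_types,
      is_skip = function(type) type %in% varshney_skip_types
    ),
    wormwiring = list(
      pre = "Origin", post = "Target", type = "Type", n = "Number of Connections",
      nt = "Neurotransmitter",
      is_gap = function(type) type == "GapJunction",
      is_chem = function(type) type == "Send",
      is_skip = function(type) rep(FALSE, length(type))
    ),
    stop("unknown connectome dialect: ", dialect)
  )
}

#' Read a connectome wiring table
#'
#' Parses a CSV wiring table in one of the two public spreadsheet layouts.
#' The `varshney` dialect uses headers `Neuron 1, Neuron 2, Type, Nbr` with
#' `Type` in {S, Sp, R, Rp, EJ, NMJ}: S/Sp/NMJ rows are chemical connections
#' from Neuron 1 to Neuron 2, R/Rp rows are the mirrored duplicates of S/Sp
#' rows and are skipped, EJ rows are gap junctions. The `wormwiring` dialect
#' uses headers `Origin, Target, Type, Number of Connections` with `Type` in
#' {Send, GapJunction} and an optional `Neurotransmitter` column (blank or
#' absent entries become `"UNKNOWN"`).
#'
#' Self-connections are dropped with a warning; duplicate rows for the same
#' ordered pair are merged with contact counts summed; gap junctions are
#' stored once per unordered pair.
#'
#' @param file Path to a CSV file, or a character vector of CSV lines.
#' @param dialect `"varshney"` or `"wormwiring"`.
#' @param cell_classes Optional named character vector mapping cell names to
#'   classes; unnamed cells are classified by [guess_cell_class()].
#' @return A [connectome].
#' @export
read_connectome_table <- function(file, dialect = c("wormwiring", "varshney"),
                                  cell_classes = NULL) {
  dialect <- match.arg(dialect)
  spec <- dialect_spec(dialect)
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    raw <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  } else {
    raw <- readr::read_csv(I(paste(file, collapse = "\n")),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  }
  required <- c(spec$pre, spec$post, spec$type, spec$n)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("connectome table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  pre <- trimws(raw[[spec$pre]])
  post <- trimws(raw[[spec$post]])
  type <- trimws(raw[[spec$type]])
  n_raw <- trimws(raw[[spec$n]])
  n <- suppressWarnings(as.numeric(n_raw))
  bad <- which(is.na(n) | n < 1 | n != round(n))
  if (length(bad) > 0) {
    stop(sprintf("invalid contact count '%s' at data row %d (must be integer >= 1)",
                 n_raw[bad[1]], bad[1]))
  }
  n <- as.integer(n)
  nt <- if (!is.null(spec$nt) && spec$nt %in% names(raw)) {
    normalise_transmitter(raw[[spec$nt]])
  } else {
    rep("UNKNOWN", nrow(raw))
  }

  keep <- !spec$is_skip(type)
  self <- pre == post
  if (any(self & keep)) {
    warning("dropping ", sum(self & keep), " self-connection row(s): ",
            paste(unique(pre[self & keep]), collapse = ", "))
    keep <- keep & !self
  }
  is_gap <- spec$is_gap(type)
  is_chem <- spec$is_chem(type)
  unknown_type <- keep & !is_gap & !is_chem
  if (any(unknown_type)) {
    stop("unrecognised connection Type '", type[which(unknown_type)[1]],
         "' for dialect ", dialect)
  }

  chem <- tibble::tibble(pre = pre, post = post, n_contacts = n,
                         neurotransmitter = nt)[keep & is_chem, ]
  if (nrow(chem) > 0) {
    chem <- dplyr::summarise(
      dplyr::group_by(chem, .data$pre, .data$post),
      n_contacts = sum(.data$n_contacts),
      neurotransmitter = resolve_transmitters(.data$neurotransmitter),
      .groups = "drop")
  }

  elec <- tibble::tibble(cell_a = pmin(pre, post), cell_b = pmax(pre, post),
                         n_contacts = n)[keep & is_gap, ]
  if (nrow(elec) > 0) {
    elec <- dplyr::summarise(
      dplyr::group_by(elec, .data$cell_a, .data$cell_b),
      n_contacts = max(.data$n_contacts), .groups = "drop")
  }

  cell_names <- sort(unique(c(chem$pre, chem$post, elec$cell_a, elec$cell_b)))
  # Per-cell neurotransmitter: annotation of the cell when it is presynaptic.
  cell_nt <- rep("UNKNOWN", length(cell_names))
  names(cell_nt) <- cell_names
  if (nrow(chem) > 0) {
    ann <- dplyr::summarise(dplyr::group_by(chem, .data$pre),
                            nt = resolve_transmitters(.data$neurotransmitter),
                            .groups = "drop")
    cell_nt[ann$pre] <- ann$nt
  }
  classes <- guess_cell_class(cell_names)
  if (!is.null(cell_classes)) {
    hit <- intersect(cell_names, names(cell_classes))
    classes[match(hit, cell_names)] <- cell_classes[hit]
  }
  cells <- tibble::tibble(name = cell_names, cell_class = classes,
                          neurotransmitter = unname(cell_nt))
  cells <- dplyr::bind_cols(cells, default_positions(cells))
  connectome(cells = cells, chemical = chem, electrical = elec,
             source_tag = dialect)
}

# When duplicate rows disagree, keep the single informative annotation.
resolve_transmitters <- function(nt) {
  known <- setdiff(unique(nt), "UNKNOWN")
  if (length(known) == 0) "UNKNOWN" else known[1]
}

#' Guess the class of a cell from its canonical name
#'
#' Muscles follow the MDL/MDR/MVL/MVR quadrant naming; ventral-cord motor
#' neuron classes (AS, DA, DB, DD, VA, VB, VC, VD plus PDA/PDB) are
#' recognised by prefix; everything else defaults to interneuron.
#'
#' @param name Character vector of cell names.
#' @return Character vector of classes.
#' @export
guess_cell_class <- function(name) {
  out <- rep("interneuron", length(name))
  out[grepl("^M[DV][LR][0-9]+$", name)] <- "muscle"
  out[grepl("^(AS|DA|DB|DD|VA|VB|VC|VD|PDA|PDB)[0-9]*$", name)] <- "motorneuron"
  out
}

# Abstract soma coordinates: cells on a straight anterior-posterior axis in
# canonical name order; muscles at their quadrant-row positions.
default_positions <- function(cells) {
  n <- nrow(cells)
  pos <- tibble::tibble(x = double(n), y = double(n), z = double(n))
  if (n == 0) return(pos)
  neurons <- which(cells$cell_class != "muscle")
  pos$x[neurons] <- 50 * (seq_along(neurons) - 1)
  muscles <- which(cells$cell_class == "muscle")
  if (length(muscles) > 0) {
    lay <- layout_muscles()
    m <- match(cells$name[muscles], lay$name)
    known <- !is.na(m)
    pos$x[muscles[known]] <- lay$x[m[known]]
    pos$y[muscles[known]] <- lay$y[m[known]]
    pos$z[muscles[known]] <- lay$z[m[known]]
  }
  pos
}

#' Write a connectome as a wormwiring-dialect CSV
#'
#' Emits one row per chemical connection (`Type = Send`) and one per
#' gap-junction pair (`Type = GapJunction`), with the `Neurotransmitter`
#' column filled for chemical rows. Reading the file back with
#' [read_connectome_table()] reproduces the connectome.
#'
#' @param x A [connectome].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_connectome_csv <- function(x, file) {
  chem <- tibble::tibble(
    Origin = x$chemical$pre, Target = x$chemical$post, Type = "Send",
    `Number of Connections` = x$chemical$n_contacts,
    Neurotransmitter = x$chemical$neurotransmitter)
  elec <- tibble::tibble(
    Origin = x$electrical$cell_a, Target = x$electrical$cell_b,
    Type = "GapJunction", `Number of Connections` = x$electrical$n_contacts,
    Neurotransmitter = "")
  out <- dplyr::arrange(dplyr::bind_rows(chem, elec),
                        .data$Type, .data$Origin, .data$Target)
  readr::write_csv(out, file, progress = FALSE)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Subsetting and synthesis

#' Restrict a connectome to a subset of cells
#'
#' Keeps exactly the named cells and the connections with both endpoints in
#' the subset.
#'
#' @param x A [connectome].
#' @param names Character vector of cell names, all present in `x`.
#' @return A [connectome].
#' @export
subset_connectome <- function(x, names) {
  unknown <- setdiff(names, x$cells$name)
  if (length(unknown) > 0) {
    stop("unknown cell name(s): ", paste(sort(unknown), collapse = ", "))
  }
  connectome(
    cells = x$cells[x$cells$name %in% names, ],
    chemical = x$chemical[x$chemical$pre %in% names & x$chemical$post %in% names, ],
    electrical = x$electrical[x$electrical$cell_a %in% names &
                              x$electrical$cell_b %in% names, ],
    source_tag = x$source_tag)
}

#' Generate a synthetic connectome
#'
#' Draws a random wiring diagram with the statistical signatures of the real
#' one that matter for model building: a division into neurons and muscles,
#' directed chemical connections (muscles never presynaptic to neurons),
#' unordered gap-junction pairs among neurons, contact counts from a geometric
#' distribution shifted to a minimum of one, and a chosen fraction of
#' GABAergic (hence inhibitory) neurons. Deterministic for a fixed seed.
#'
#' @param n_neurons,n_muscles Positive integers.
#' @param chem_density Probability of a chemical connection for each ordered
#'   neuron pair (and each neuron-to-muscle pair).
#' @param gap_density Probability of a gap junction for each unordered neuron pair.
#' @param gaba_fraction Fraction of neurons transmitting GABA.
#' @param contact_mean Mean contact count (geometric, minimum 1).
#' @param seed Integer seed.
#' @return A [connectome].
#' @export
generate_synthetic_connectome <- function(n_neurons, n_muscles = 0,
                                          chem_density = 0.05,
                                          gap_density = 0.02,
                                          gaba_fraction = 0.25,
                                          contact_mean = 3, seed = 1) {
  if (n_neurons < 1 || n_muscles < 0) stop("sizes must be positive")
  probs <- c(chem_density, gap_density, gaba_fraction)
  if (any(probs < 0 | probs > 1)) stop("densities and gaba_fraction must lie in [0, 1]")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  neuron_names <- sprintf("SYN%03d", seq_len(n_neurons))
  muscle_names <- if (n_muscles > 0) layout_muscles()$name[seq_len(n_muscles)] else character()
  nt <- ifelse(stats::runif(n_neurons) < gaba_fraction, "GABA", "Acetylcholine")

  draw_counts <- function(k) 1L + stats::rgeom(k, prob = 1 / max(contact_mean, 1))

  pairs <- expand.grid(pre = neuron_names, post = c(neuron_names, muscle_names),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$pre != pairs$post, ]
  hit <- stats::runif(nrow(pairs)) < chem_density
  chem <- tibble::tibble(pre = pairs$pre[hit], post = pairs$post[hit])
  chem$n_contacts <- draw_counts(nrow(chem))
  chem$neurotransmitter <- nt[match(chem$pre, neuron_names)]

  gp <- utils::combn(neuron_names, 2)
  ghit <- stats::runif(ncol(gp)) < gap_density
  elec <- tibble::tibble(cell_a = gp[1, ghit], cell_b = gp[2, ghit])
  elec$n_contacts <- draw_counts(nrow(elec))

  cells <- tibble::tibble(
    name = c(neuron_names, muscle_names),
    cell_class = c(rep("interneuron", n_neurons), rep("muscle", length(muscle_names))),
    neurotransmitter = c(nt, rep("UNKNOWN", length(muscle_names))))
  cells <- dplyr::bind_cols(cells, default_positions(cells))
  connectome(cells = cells, chemical = chem, electrical = elec,
             source_tag = sprintf("synthetic(seed=%d)", seed))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
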