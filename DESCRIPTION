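Package: wormcircuit
Title: Connectome-Based Neural Circuit Models of the C. elegans Nervous System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds executable network models of the Caenorhabditis elegans
    nervous system and body-wall musculature from connectome wiring tables,
    at selectable levels of biophysical detail: leaky integrate-and-fire or
    single-compartment conductance-based cells, spike-triggered or graded
    (analogue) chemical synapses, and gap junctions.  Includes a built-in
    fixed-step simulator recording membrane potential, intracellular calcium
    and spike times, a forward-locomotion circuit of command interneurons,
    B- and D-type motor neurons and the four muscle quadrants driven by a
    central-pattern-generator stimulus, quantitative travelling-wave analysis
    of muscle calcium activity, and declarative network export in a
    NeuroML-style XML subset.
License: MIT
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    xml2,
    ggplot2,
    generics,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
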