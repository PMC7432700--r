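Package: synmorph
Title: Synthetic Serial-Section EM Morphometry of Synaptic Boutons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative three-dimensional morphometry of cortical synaptic
    boutons from serial-section electron microscopy annotations: contour-stack
    alignment and 3D reconstruction (Cavalieri volumes, lofted surface areas),
    active-zone metrics (presynaptic-density extraction by a 30 nm apposition
    rule, postsynaptic-density area by the contour-length-ratio estimator,
    synaptic-cleft widths), and perimeter-based classification of synaptic
    vesicle pools (readily releasable, recycling, resting). A ground-truth
    scene generator emulates serial-section TEM and anisotropic FIB-SEM
    sampling of human neocortical boutons so every pipeline stage can be
    validated against known geometry, and a statistics layer reproduces the
    field's per-subject aggregation and Kruskal-Wallis/post-hoc U workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    mgcv,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
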