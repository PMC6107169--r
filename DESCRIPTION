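Package: h5layout
Title: Chunk Layout Planning and I/O Cost Modelling for HDF5 Time-Series
    Simulation Output
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Plans HDF5 chunk shapes for multidimensional simulation output
    with a dimension-agnostic algorithm that targets a chunk size in bytes
    while minimising wasted space at the dataset edge. Provides analytic
    models of row-major serialisation and contiguous-segment read cost, of
    Lustre-style striping (round-robin placement over object storage
    targets, stripe-count heuristics, chunk-to-stripe alignment), and an
    HDF5 writer with a time-window write cache that aggregates per-timestep
    writes into chunk-sized flushes. Includes a synthetic cardiac-simulation
    output generator (transmembrane and extracellular potentials with known
    activation times) and a benchmark driver that compares chunking
    strategies on the post-processing access patterns of activation-time
    and peak-voltage mapping and timestep-slab conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rhdf5lib
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
SystemRequirements: GNU make
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
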