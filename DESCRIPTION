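Package: bhmap
Title: Machine-Learning-Augmented Basin-Hopping Exploration of Molecular
    Potential Energy Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping molecular potential energy surfaces with the
    basin-hopping algorithm and interpreting the resulting minima libraries
    with unsupervised learning. Provides interatomic distance-matrix and
    mass-weighted cosine similarity functions, WPGMA and Ward agglomerative
    clustering with dendrogram and Newick export, 2D multidimensional
    scaling, artificial-force-field and constrained Monte Carlo
    interpolation of intermediate geometries (including transition-state
    guess export), an IR spectral-matching pipeline (frequency scaling,
    Lorentzian broadening, per-region normalization, scaled similarity
    ranking), and temperature-dependent Boltzmann-weighted collision cross
    sections with Mason-Schamp mobilities. Includes pluggable model
    potentials (Lennard-Jones clusters, torsional chains) and seeded
    synthetic-data generators so every stage is testable without an
    electronic-structure engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
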