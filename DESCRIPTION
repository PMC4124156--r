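Package: covhelix
Title: Helix-Helix Contact Detection from Evolutionary Couplings and
    Membrane-Protein Model Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring transmembrane helix-helix packing from
    residue-residue evolutionary couplings. Reads and redundancy-filters
    multiple sequence alignments, computes coupling-strength matrices
    (mutual information with average-product correction, or mean-field
    direct-coupling analysis), detects helix-helix interactions by sliding
    a periodicity-aware weighted pattern over the coupling matrix and
    aggregating per-cell Bayesian evidence, and calibrates the resulting
    raw scores into posterior probabilities. Downstream utilities rank
    residue pairs into modeling restraints with exclusion rules, build
    crude ideal-helix bundles from contact graphs and lipid-exposure
    labels, compare structures (Cbeta distances, Kabsch superposition,
    smoothed C-alpha deviation profiles), and compute membrane trajectory
    observables (leaflet-resolved thickness maps, positional-variance
    flexibility, geometric hydrogen bonds, height-resolved hydropathy,
    local energy smoothing). Seeded synthetic-data generators make the
    whole pipeline testable without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
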