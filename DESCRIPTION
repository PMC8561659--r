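Package: microload
Title: Live Microbial Load Quantification and Compositional Dynamics for
    Longitudinal Saliva Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies live microbial load in longitudinal saliva samples by
    combining flow-cytometry gating with counting-bead absolute calibration
    and propidium monoazide (PMA) relic-DNA removal. Provides gating of raw
    event tables into bacterial and bead populations, bead-based conversion to
    absolute concentrations, paired raw/PMA live-dead-percent-live metrics,
    qPCR standard-curve load estimation, compositional analyses on paired
    feature tables (taxonomy filtering, centred log-ratio and Aitchison
    distance, unweighted UniFrac, Faith's phylogenetic diversity with
    rarefaction, principal coordinates), per-participant convex-hull
    dispersion in ordination space, and a permutation Kruskal-Wallis test for
    grouped distances. A synthetic-cohort generator emulates the statistical
    structure of daily-dynamics and acute-perturbation saliva studies
    (perturbation kernels, relic-DNA pools, cytometry event clouds,
    chloroplast contamination) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'bookkeeping.R'
    'feature-table.R'
    'distances.R'
    'dispersion.R'
    'gating.R'
    'io.R'
    'simulate-cohort.R'
    'simulate-counts.R'
    'simulate-events.R'
    'viability.R'
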