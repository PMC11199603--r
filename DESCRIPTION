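Package: genefold
Title: Transcription-Coupled 3D Gene Folding: Contact Scoring, Meta-Gene
    Pileups and Pol II Polymer Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and model the relationship between RNA Pol II
    occupancy and the three-dimensional folding of genes. Computes
    distance-normalized (observed/expected) contact maps from binned
    chromosome-conformation-capture matrices, per-gene intra-gene contact (IC)
    and Pol II (IR) scores, and pile-up meta-gene aggregates (PMGA) of contact
    maps and coverage tracks. Includes a kinetic Monte Carlo simulator that
    couples a totally asymmetric simple exclusion process (TASEP) model of
    Pol II elongation, with optional two-state bursting promoters, to a
    self-avoiding semi-flexible polymer on an FCC lattice with valency-limited
    attraction between Pol II-bound monomers, plus observables (simulated
    contact maps and IC, radius of gyration, anomalous-diffusion MSD fits,
    burst-conditioned structure) and a synthetic-data generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
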