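Package: utrfold
Title: SHAPE-Directed Structure-Function Analysis of 5'-UTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how 5'-UTR secondary structure controls
    translation initiation. Implements tiled structure-destabilizing
    (UUAUUA) mutagenesis panels, SHAPE-MaP reactivity calling from
    per-nucleotide mutation rates (depth filtering, 2%/8% normalization,
    replicate averaging with variability masking, direct reactivities),
    a SHAPE-directed thermodynamic folding engine (minimum free energy
    structures and McCaskill partition-function pairing probabilities
    under a reduced nearest-neighbor model with per-nucleotide
    pseudo-free-energy terms), differential-reactivity detection between
    profiles, base-pair-level model comparison (sensitivity, positive
    predictive value, overall similarity), structural-landscape analysis
    of mutant panels (PCA, inertia-selected k-means groups and centroid
    structures), start-codon accessibility scoring via the
    non-equilibrium unfolding cost of the translation initiation site,
    dual-luciferase relative-translation analysis, and upstream
    open-reading-frame scanning including non-canonical (CUG) starts.
    A synthetic-data generator simulates mutational-profiling rate
    tables from planted structures and translation panels coupled to
    unfolding energies, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
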