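Package: heterodont
Title: Multi-Level Dental Morphometrics for Heterodont Dentitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies tooth-shape variation within and between jaws of
    polyphyodont dentitions (heterodonty) from 2D crown outlines. Provides
    six pairwise outline distance measures (nearest-point, position-matched,
    area-overlap, cosine-Fourier, and two angle-function based distances)
    with a bounded partial Procrustes grid search; jaw-level heterodonty
    statistics (sequential, total, dignathic, maximal); ten single-tooth
    complexity measures including an outline adaptation of orientation
    patch count; Kimura two-parameter genetic distances, neighbor-joining
    trees and normalized patristic distances; and a sliding-window
    rank-test scan of trait divergence against relatedness. A seeded
    synthetic-dentition and sequence generator supports end-to-end testing
    without digitized specimens.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
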