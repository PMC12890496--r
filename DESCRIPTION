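Package: mgendo
Title: Immune Cell Endophenotypes Separating Myasthenia Gravis Subgroups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and cross-cohort validation of cellular immune
    endophenotypes that separate early-onset from late-onset myasthenia
    gravis. Implements supervised three-group differential-abundance cell
    selection on high-dimensional cytometry data, nearest-neighbour cluster
    label transfer between cohorts with different marker panels, nested
    one-tailed Wilcoxon selection with an explicit false-positive error-rate
    calculus, one-component PLS-DA subgroup classification, thymic-pathology
    association statistics, and T cell receptor repertoire enrichment tests.
    A synthetic two-cohort study generator with planted differentially
    abundant subpopulations, paired blood/thymus samples and a TCR layer
    allows the full pipeline to be exercised and benchmarked without access
    to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    BiocNeighbors,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
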