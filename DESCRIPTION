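Package: commselect
Title: Artificial Selection of Simulated Toxin-Degrading Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual-based stochastic simulator of artificial selection on
    microbial communities bred for their ability to degrade toxic compounds.
    Species face a trade-off between investing consumed nutrients into growth
    or into toxin degradation. The package implements batch-culture rounds of
    degradation, two-stage cell growth, mutation of degradation investment and
    toxin-driven death; eleven propagation methods (no-selection, propagule,
    migrant-pool and disassembly families, with random and invasion variants);
    exhaustive enumeration and ranking of all species combinations; ecological
    stability assays; and community-level analytics (Hill-number diversity,
    Bray-Curtis beta diversity, toxin and nutrient coverage, investment,
    biomass and synergy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
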