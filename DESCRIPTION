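Package: girewire
Title: Genetic Interaction Mapping and Condition-Specific Rewiring from
    Dual-sgRNA CRISPRi Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative genetic-interaction (GI) mapping from
    pooled dual-sgRNA CRISPRi screens. Converts construct read counts into
    growth and drug phenotypes (gamma, tau, rho) normalized per population
    doubling, scores pairwise genetic interactions by quadratic regression
    of pair phenotypes against single-sgRNA phenotypes with z-normalization
    to per-query negative-control spreads, and aggregates scores to the
    gene level. Differential GI (dGI) maps quantify rewiring of the
    interaction network between an environmental and a reference condition.
    Interaction profiles are clustered by Pearson distance with average
    linkage, per map or as a consensus across conditions, and compressed to
    ontology-level matrices for coordination analysis. Includes a
    dual-guide screen simulator with planted condition-specific
    interactions, protein-protein-interaction bin enrichment, and iterative
    gene-set enrichment, so the full pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
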