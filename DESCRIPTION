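Package: commfba
Title: Community Flux Balance Analysis of Gut Microbiome Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Abundance-weighted community flux balance analysis for gut
    microbiome studies. Builds community metabolic models from per-taxon
    stoichiometric networks and relative abundances with a shared lumen
    compartment, solves growth allocation by the cooperative trade-off
    (maximal community growth followed by minimization of the sum of
    squared per-taxon growth rates), applies diet-derived exchange bounds,
    computes elasticity coefficients of exchange fluxes by log-scale
    finite differences, compares matched case/control pairs by
    elasticity-variance width, computes alpha and beta diversity indices
    (Chao1, Shannon, Simpson, Bray-Curtis, UniFrac) from first principles,
    and fits probiotic doses by least squares. Ships a synthetic-data
    layer (toy genome-scale models, paired abundance tables, diet
    specifications, phylogenies) so the whole pipeline runs without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    quadprog,
    ape,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
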