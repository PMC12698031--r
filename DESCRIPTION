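Package: pondFD
Title: Functional Diversity, Null Models and Assembly Rules for Pond
    Zooplankton Communities
Version: 0.1.0
Authors@R: person("pondFD", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Trait-based community assembly analysis for pond zooplankton
    along a eutrophication gradient. Computes Gower dissimilarities over
    mixed ordinal/categorical functional traits (Podani's extension),
    embeds species in a principal-coordinates trait space, and derives
    per-sample functional diversity indices (FRic, FEve, FDiv, FDis,
    Rao's quadratic entropy, functional redundancy) and community-weighted
    means of trait categories. Constrained null models ('c0' for incidence
    and 'c0_samp' for biomass matrices) yield standardized effect sizes,
    which are tested against zero and mapped to assembly-rule verdicts
    (habitat filtering, limiting similarity, trait convergence or
    divergence) for the whole dataset and per trophic state. A synthetic
    fishpond generator with known assembly regimes (neutral, environmental
    filtering, limiting similarity) supports end-to-end validation without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
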