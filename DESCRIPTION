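Package: foundweb
Title: Food-Web Topology, Null-Model Removal and Facilitation Analysis for
    Foundation-Species Ecosystems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct dichotomous (binary, directed) trophic
    networks from edge-list or adjacency tables, prune implausible links with
    a rare-species filter, an expert forbidden-link list and a Bayesian
    stable-isotope mixing model, and compute a nineteen-metric food-web
    topology panel (species number, link density, connectance, trophic and
    guild fractions, trophic levels, chain lengths, trophic similarity,
    clustering, path length, compartmentalization). Implements a
    random-removal null model that prunes foundation-species-dominated webs
    to the richness of paired bare-area webs, a synthetic-study generator
    (niche-model webs, isotope simulation, random or guild-targeted
    facilitation), and the comparison layer: per-metric linear mixed models
    with Satterthwaite F-tests and Tukey grouping letters, covariance PCA
    across webs, and the PC1 contrast between web types.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    lmerTest,
    emmeans,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
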