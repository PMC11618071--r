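Package: densiforest
Title: Community Wood Density Mapping, Phylogenetic Signal and Forest
    Biomass from Tree Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for scaling wood density from trait databases and
    individual-tree forest inventories to community and map level.
    Builds species- and genus-level wood density lookup tables with
    source-concordance and taxonomic variance diagnostics, computes
    basal-area-weighted community wood density (CWD) with coverage and
    census filters, quantifies phylogenetic signal (Pagel's lambda,
    Blomberg's K, order-level conservatism randomization tests), trains
    buffer-zone bootstrap ensembles of random-forest regressors with
    pixel-wise uncertainty maps, classifies interpolation versus
    extrapolation through bivariate principal-component convex hulls,
    screens and ranks environmental drivers with recursive partitioning
    of disturbance effects, and converts CWD and growing-stock volume
    into living tree biomass with a constant-density counterfactual.
    A deterministic synthetic-world generator with known ground truth
    (phylogeny, traits, landscape, plots) exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    ape,
    lme4,
    mgcv,
    ranger,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
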