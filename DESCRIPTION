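Package: pollinet
Title: Pollination Networks from Visit Surveys and Pollen DNA Metabarcoding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and compares bipartite plant-pollinator networks derived
    from direct insect-visit surveys and from pollen DNA metabarcoding read
    counts. Interactions are called from sequence-count tables by a
    contamination-motivated read threshold; networks are assembled at three
    resolution levels (pollinator group x floral morph group, species x
    species, individual x species); a full suite of network indices
    (connectance, nestedness temperature, Barber bipartite modularity, H2',
    d', interaction evenness, extreme specialization, degree-distribution
    fits and frequency-connectivity regressions) is computed from first
    principles; fixed-marginal (Patefield) null-model confidence intervals
    and size-matched multinomial rarefaction tests support like-for-like
    comparison of the two network types. A synthetic-data generator with a
    known ground truth (skewed abundances, group-structured preferences,
    multi-visit pollen accumulation, airborne-grass background contamination)
    makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Metagenomics, Sequencing
RoxygenNote: 7.3.3
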