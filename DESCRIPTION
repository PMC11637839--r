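Package: linetester
Title: Line-by-Tester Combining Ability, Heterosis and Heterotic Grouping
    for Multi-Environment Maize Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complete quantitative-genetics workflow for line-by-tester
    testcross trials grown in incomplete-block (alpha-lattice) designs across
    several environments: validated plot-level CSV input, fixed-effects
    adjusted genotype means (BLUEs), balanced line-by-tester analysis of
    variance with GCA/SCA partition, method-of-moments variance components,
    additive and dominance variances with broad- and narrow-sense
    heritability, mid-parent, better-parent and economic heterosis,
    heterotic grouping of parents from Z-scored GCA effects (Ward.D2
    clustering with cluster-count selection and dendrogram comparison), and
    the inter-trait correlation analyses breeders use alongside them.  A
    seeded trial simulator with known genetic architecture provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
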