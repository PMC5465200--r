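Package: ystr
Title: Y-Chromosomal STR and Haplogroup Population Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing paternal (Y-chromosomal) population structure
    from SNP-defined haplogroups and short-tandem-repeat (STR) haplotypes.
    Provides haplogroup assignment on a configurable marker tree, population
    haplogroup-frequency tables and diversity statistics, Nei genetic
    distances with MDS and PCA ordination, three-level AMOVA with permutation
    tests, Mantel tests of genetic versus geographic distance, modal-haplotype
    and related-haplotype (descent cluster) detection on 15-locus Y-STR
    profiles, median-joining haplotype networks with population-enriched clade
    delineation, rho and ASD (average squared distance) TMRCA dating under the
    stepwise mutation model, and a clan-expansion simulator with recorded
    genealogical truth for estimator validation. A pipeline driver produces a
    reproducibility manifest from a single seeded configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
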