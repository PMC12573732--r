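Package: aphidQTL
Title: QTL Mapping and Regional Heritability for an Aphid Host-Race F2 Cross
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for F2 intercross quantitative
    genetics in the pea aphid, where males are achiasmatic (all recombination
    is maternal). Provides a synthetic-cross generator (founders, F2
    genotypes with female-only recombination, behavioural acceptance and
    survival phenotypes, clustered chemosensory gene positions), marker QC
    and de-novo linkage-map construction, Marey-map rearrangement and
    recombination-suppression detection with signed-reversal inversion
    counting, hidden-Markov genotype probabilities with nonparametric and
    two-part single-QTL genome scans and permutation thresholds, regional
    heritability mapping with genomic relatedness matrices and a
    regional-matrix permutation null, analytic QTL detection power, and
    gene-region overlap and enrichment tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
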