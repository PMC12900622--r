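Package: mtphylogeo
Title: Intraspecific Phylogeography from Mitochondrial Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of aligned mitochondrial sequences:
    haplotype and nucleotide diversity, Gst/Nst differentiation with
    permutation tests, hierarchical AMOVA with Phi-statistics, pairwise
    Fst and island-model gene-flow estimates, Tajima's D and Fu's Fs
    neutrality tests, mismatch-distribution fitting under the sudden
    demographic expansion model (tau, theta0, theta1, SSD, raggedness,
    expansion-time conversion), and median-joining haplotype networks.
    Includes a structured-coalescent simulator (hierarchical island model
    with optional sudden expansion) for generating synthetic datasets with
    the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
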