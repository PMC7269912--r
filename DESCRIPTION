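Package: clgkit
Title: Ancestral Chordate Linkage Groups, Genome Duplication and Retention Asymmetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs ancestral chordate linkage groups (CLGs) from
    cross-species gene maps and mutual-best-hit orthology, detects synteny
    breakpoints with a windowed discontinuity statistic, tests CLG-chromosome
    associations against a hypergeometric null with Bonferroni correction,
    paints duplicated genomes by local CLG ancestry, and analyses paralogue
    retention asymmetry between subgenomes after successive whole-genome
    duplications (autotetraploidy versus allotetraploidy), including a
    uniform-null bootstrap asymmetry test, Hartigan's dip test of bimodality,
    cross-species retention correlations and a fusion-concordance permutation
    test. Ships a genome-evolution simulator that generates multi-species gene
    maps with known truth labels so every stage of the pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
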