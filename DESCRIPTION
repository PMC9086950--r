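Package: haplodrift
Title: Forward-Time Simulation of Genome Evolution in Haplodiploid and
    Diploid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based forward-time simulation of the fates of
    neutral, advantageous and deleterious mutations in haplodiploid
    populations (haploid males from unfertilized eggs, diploid females)
    and in matched diploid populations. Males inherit a single recombined
    maternal genome and carry an empty "null" second genome; hemizygous
    male carriers of a mutation with selection coefficient s have relative
    fitness 1 + s. Includes sparse-genome meiosis with crossover
    recombination and de novo mutation, fitness-proportional reproduction
    with non-overlapping generations and a fixed census, fixation and loss
    tracking, an exact Markov-chain oracle for single-locus fixation
    probabilities at small census sizes, replicated treatment grids with
    Wilcoxon rank-sum comparisons between population types, and VCF 4.2
    export of segregating variants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
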