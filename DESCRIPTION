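Package: riverpopgen
Title: Multi-Marker Population Genetics for River Metapopulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic analysis of riverine metapopulations typed
    for a fast-evolving mitochondrial sequence marker and nuclear
    microsatellites. Provides sequence diversity and neutrality statistics
    (haplotype and nucleotide diversity, Tajima's D, Fu and Li's D* and F*,
    Fu's Fs, R2, mismatch distributions), Hudson-family differentiation
    statistics with permutation nulls, AMOVA, exact tests on haplotype and
    genotype tables via Markov chains, Hardy-Weinberg tests, Wright
    F-statistics, Nei distances, assignment and first-generation-migrant
    detection, four microsatellite demographic-change tests (imbalance
    index, allele-size-kurtosis expansion index, M-ratio with simulated
    equilibrium critical values, intralocus kurtosis and interlocus
    variance tests), spatial genetic structure (Mantel tests, distance-class
    correlograms, network autocorrelation, distograms, inverse-distance
    genetic landscapes), median-joining haplotype networks with
    rho-statistic dating, and a seeded structured-coalescent generator for
    river-network metapopulations with sex-biased migration, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    igraph,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'synthetic.R'
    'msat-demography.R'
    'msat-structure.R'
    'network.R'
    'pipeline.R'
    'riverpopgen-package.R'
    'seq-diversity.R'
    'seq-structure.R'
    'spatial.R'
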