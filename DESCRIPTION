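Package: introscan
Title: Genome-Wide Introgression, Divergence and Discordance Scans
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for genome-wide analyses of introgression,
    divergence and phylogenetic discordance in small radiations sampled with
    one to a few diploid genomes per species. Reads filtered multi-sample
    VCFs into a biallelic genotype matrix, computes missing-data-aware
    windowed nucleotide diversity (pi), absolute divergence (dxy) and
    Weir-Cockerham FST with ratio-of-sums aggregation, four-taxon
    site-pattern statistics (Patterson's D with block-jackknife
    significance, the f4-ratio, windowed fdM, and the f-branch metric on a
    guide tree), tree-based discordance measures (normalized Robinson-Foulds
    distances, topology weighting across multi-sample taxa, gene and site
    concordance factors), and a loss-of-function scan of aligned coding
    sequences (large deletions, frameshifts, premature stop codons, and
    substitutions in named protein domains). Includes a
    multispecies-coalescent simulator with directed migration pulses,
    infinite-sites mutation sprinkling and CDS mutation injection, so every
    analysis can be exercised and calibrated on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
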