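Package: hp1tools
Title: Motif Scanning, Peak Co-Localization and Heterochromatin Border
    Calling for HP1a Interactome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for three computational analyses around the Drosophila
    heterochromatin protein 1a (HP1a) interactome: scanning protein
    sequences for the chromoshadow-domain-binding pentapeptide PxVxL and
    its degenerate variants LxVxL and CxVxL; assessing co-localization of
    ChIP-seq peak sets with a chromosome-aware randomization (permutation)
    test yielding empirical p-values and z-scores; and calling the
    heterochromatin-euchromatin "epigenomic border" on a chromosome arm as
    the point where the binned median of peak summit heights decays below
    the genome-wide median. Includes seeded synthetic-data generators
    (proteomes with planted motifs, peak pairs with a controlled overlap
    fraction, stepped peak-height landscapes) that emit exact ground truth
    for testing, plus readers and writers for FASTA, BED3/BED6, ENCODE
    narrowPeak and chrom.sizes, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
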