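Package: karyodiv
Title: Comparative DNA Variation Between Autosomes and Sex Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genetic analysis of multi-sample variant
    calls for comparing patterns of DNA variation between autosomes, the X
    chromosome and the Y chromosome. Computes nucleotide diversity,
    Watterson's theta and Tajima's D in fixed non-overlapping windows from
    VCF allele counts, Ka/Ks selection-pressure ratios from consequence
    annotations, variant-density summaries, hotspot and empty-window
    classification against gene annotation and assembly gaps, and a battery
    of rank-based and goodness-of-fit tests with Bonferroni correction.
    Includes a self-contained coalescent-style simulator that emits
    reference FASTA, GFF3 and multi-sample VCF fixtures with known ground
    truth, including hemizygous Y genotypes and per-chromosome-class
    effective-size scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
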