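Package: hapcsq
Title: Haplotype-Aware Variant Consequence Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint functional consequence prediction for in-phase variants.
    Given a phased VCF, a GFF3 gene annotation and a reference FASTA,
    determines the combined effect of all variants carried on each haplotype
    within a transcript, resolving multi-nucleotide changes within one codon,
    frame-restoring indel pairs and codon changes that span introns in the
    spliced transcript. Unique consequences are written to a per-site INFO
    tag and per-sample, per-haplotype assignments to an interleaved integer
    bitmask FORMAT tag. A localized single-record mode is provided for
    comparison, along with a synthetic fixture generator and an independent
    whole-protein diff oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR,
    rtracklayer
Config/testthat/edition: 3
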