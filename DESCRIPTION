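Package: orgbarcode
Title: Organellar Super-Barcode Evaluation for Species Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate complete organellar genomes (mitogenomes and
    plastomes) as species-level "super-barcodes". Detects plastid-derived
    regions (MTPTs) and repeats in a mitogenome by seeded local alignment
    with Karlin-Altschul e-values, selects clean barcode fragments, calls
    molecular diagnostic characters (MDCs) per species against congeneric
    references, quantifies species-discrimination efficiency, computes
    sliding-window nucleotide diversity and GC tracks, contrasts relative
    synonymous codon usage (RSCU) and MILC codon-usage bias between
    organelles, and compares organellar phylogenies (Robinson-Foulds,
    tanglegram). A synthetic-data generator provides ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    ape,
    phangorn,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
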