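Package: rhizomir
Title: Plant miRNA Detection and Target Prediction in Rhizosphere Bacteria
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for cross-kingdom small-RNA analysis in the rhizosphere:
    calls plant microRNAs that are compartment-specific (rhizosphere, root, or
    rhizosphere-bacterial fraction versus bulk soil) from small RNA-seq count
    tables; predicts miRNA target sites on bacterial genomes with a
    position-weighted expectation score in the psRNAtarget tradition; annotates
    and filters predicted sites by distance to the nearest coding sequence;
    screens miRNA sequences against bacterial genome collections to exclude a
    bacterial origin; generates scrambled sequence controls; and tests the
    overlap between predicted-target and differentially expressed gene sets
    against a hypergeometric and permutation null. Includes seeded synthetic
    generators (genomes with planted target sites, CDS annotations, count
    tables) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tools,
    yaml
Config/testthat/edition: 3
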