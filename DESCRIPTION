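Package: casmei
Title: Cas9-Targeted Nanopore Enrichment Analysis of Mobile Element Insertions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for Cas9-targeted nanopore sequencing of mobile element
    insertions (MEIs): subfamily-specific guide RNA design from consensus
    alignments with k-mer frequency screening and tiering, theoretical
    capture-bound estimation for a chosen guide, quality filtering and
    end-scan classification of nanopore reads into on/close/off-target
    categories, pre-masking of annotated reference repeats, non-reference MEI
    calling from insertion and soft-clip signals with detection of
    target-primed reverse transcription hallmarks (target site duplications,
    poly(A) tracts, endonuclease cleavage motifs, 5' inversions), and
    downstream analyses (cleavage-site distributions, strand bias, saturation
    curves, trio transmission, recurrence dot plots). A seeded synthetic-data
    generator emulates reference genomes with implanted repeat families,
    diploid donors carrying hallmark-bearing insertions, and Cas9-cut
    nanopore runs with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
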