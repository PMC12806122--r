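Package: promforge
Title: Design of State-Specific Synthetic Promoters from Differential
    Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcription-factor binding motifs enriched in
    state-specific open-chromatin (ATAC-seq) peak sets using position
    weight matrix scanning with exact score-distribution p-values and
    ZOOPS Fisher enrichment, intersects enriched motifs across multiple
    datasets or species, and compiles the surviving motifs into synthetic
    promoters: tandem arrays of consensus binding sites with short
    screened spacers placed upstream of a minimal core promoter. Includes
    a seeded simulator that plants motif instances into Markov background
    sequences so the whole pipeline can be exercised against known truth,
    plus readers and writers for BED, FASTA, JASPAR and Homer motif
    files, count-matrix TSVs and annotated GenBank output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
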