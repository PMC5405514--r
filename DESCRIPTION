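Package: tertarch
Title: Comparative Analysis of TERT Gene Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative analysis of the exon-intron architecture
    of telomerase reverse transcriptase (TERT) genes across species:
    projection of intron positions onto protein coordinates and
    cross-species classification of introns as conserved or
    species-specific, alignment-based transfer of canonical motif
    annotations from a reference TERT, discovery of lineage-restricted
    conserved sequence blocks reported as degenerate consensus strings,
    and structural classification of alternatively spliced variants
    (exon skipping, intron retention, splice-site mutations) with
    reading-frame and domain-truncation calls. A gene-family simulator
    with full ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    ape,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
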