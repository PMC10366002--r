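Package: bestop
Title: Design and Genome-Wide Modelling of STOP-Codon-Introducing Base-Editor Guides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing cytosine-base-editor (CBE) guide RNAs that
    introduce premature STOP codons into bacterial coding sequences. Scans an
    annotated genome for protospacers adjacent to a PAM whose editing-window
    C-to-T conversions create TAA, TAG or TGA in frame, aggregates the results
    into genome-wide targeting-space and coverage statistics across PAM
    variants (NGG, NG, NAA, ...), searches off-target sites allowing
    mismatches and DNA/RNA bulges and associates them with observed variants,
    screens pre-tRNAs and assembles multiplex sgRNA expression arrays
    (msgRNA, mCRISPR and tRNA-sgRNA fusion cassettes), and generates
    synthetic annotated genomes with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    vcfR,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
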