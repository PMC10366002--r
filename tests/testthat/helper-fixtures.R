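# Hand-built fixtures with fully known expected outcomes.

# Coding sequence: ATG, 5x AAA, CAG (codon 6, coding pos 19), 5x AAA,
# AGG (the only NGG PAM), AAA x6, TAA. The protospacer [17..36] has a
# single window C at offset -18; editing it gives CAG -> TAG.
cag_fixture <- function() {
  coding <- paste0("ATG", strrep("AAA", 5), "CAG", strrep("AAA", 5),
                   "AGG", strrep("AAA", 6), "TAA")
  stopifnot(nchar(coding) == 60)
  seqn <- paste0("TTTT", coding, "TTTT")
  annotated_genome("FIX1", seqn,
                   data.frame(id = "geneA", start = 5, end = 64, strand = "+",
                              pseudo = FALSE))
}

# Same gene but the editable CAG sits at coding position 49 (fraction
# 49/60 = 0.817); the AGG PAM lies in the 3' flank, outside the CDS.
cag_late_fixture <- function() {
  coding <- paste0("ATG", strrep("AAA", 15), "CAG", strrep("AAA", 2), "TAA")
  stopifnot(nchar(coding) == 60)
  seqn <- paste0("TTTT", coding, "TTTTTT", "AGG", "TT")
  annotated_genome("FIX2", seqn,
                   data.frame(id = "geneA", start = 5, end = 64, strand = "+",
                              pseudo = FALSE))
}

# Quiet genome: CDSs with no C and no G on the coding strand (codons
# ATG/AAT...TAA only) so no STOP-capable protospacer can exist until one
# is planted. Intergenic filler is T-rich for the same reason.
quiet_genome <- function(n_genes = 10L, codons = 40L, id = "QUIET") {
  pieces <- character(0)
  feats <- list()
  pos <- 1L
  for (g in seq_len(n_genes)) {
    ig <- 40L
    pieces <- c(pieces, strrep("T", ig))
    pos <- pos + ig
    coding <- paste0("ATG", strrep("AAT", codons - 2L), "TAA")
    strand <- if (g %% 2L == 0L) "-" else "+"
    pieces <- c(pieces, if (strand == "+") coding else bestop::revcomp(coding))
    feats[[g]] <- data.frame(id = sprintf("Q_%03d", g), start = pos,
                             end = pos + nchar(coding) - 1L, strand = strand,
                             pseudo = FALSE)
    pos <- pos + nchar(coding)
  }
  pieces <- c(pieces, strrep("T", 40L))
  annotated_genome(id, paste(pieces, collapse = ""), do.call(rbind, feats),
                   circular = FALSE)
}

# Small random genome for oracle-equality tests.
small_genome <- function(seed, n_genes = 5L, mean_len = 450) {
  generate_annotated_genome(
    synthetic_genome_spec(n_genes = n_genes, gene_length_mean = mean_len,
                          gene_length_sd = 90, intergenic_mean = 60,
                          intergenic_sd = 15, circular = FALSE),
    seed = seed)$genome
}

# Mirror a genome: reverse-complement the sequence and flip annotations.
mirror_genome <- function(genome) {
  n <- nchar(genome$sequence)
  ft <- genome$features
  if (nrow(ft)) {
    ft2 <- data.frame(id = ft$id, start = n - ft$end + 1L,
                      end = n - ft$start + 1L,
                      strand = ifelse(ft$strand == "+", "-", "+"),
                      pseudo = ft$pseudo)
  } else ft2 <- NULL
  annotated_genome(genome$id, revcomp(genome$sequence), ft2,
                   circular = genome$circular)
}
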