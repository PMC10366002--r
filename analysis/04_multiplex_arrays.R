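#!/usr/bin/env Rscript

# Step 4: multiplex sgRNA cassette assembly. Screens the registry tRNAs
# with the sequence-level pre-tRNA criteria (poly-U trailer, weak A/U-rich
# stem-loop near the CCA end, codon usage rank), then assembles the three
# multiplexing architectures (msgRNA, mCRISPR, mtRNA) for the top three
# clean guides found in step 2, and compares cassette sizes.

library(bestop)

genome <- read_genome("results/synthetic_genome.gb", format = "genbank")
hits <- utils::read.delim("results/ng_hits.tsv")

usage <- compute_codon_usage(extract_cds_records(genome))
parts <- default_parts_registry()
roles <- attr(parts, "roles")

for (nm in names(roles)[roles == "trna"]) {
  rep <- evaluate_pre_trna(nm, parts[[nm]], strrep("AG", 10),
                           decoded_codon = if (nm == "trna_thr") "ACA" else "ATG",
                           usage = usage)
  print(rep)
}

clean <- hits[hits$quality == "clean", ]
spacers <- toupper(utils::head(clean$protospacer_seq, 3))
stopifnot(length(spacers) == 3)

sizes <- data.frame(strategy = character(), parts = integer(), nt = integer())
for (strategy in c("msgRNA", "mCRISPR", "mtRNA")) {
  a <- build_array(spacers, strategy, parts = parts, seed = 20231L)
  write_array_fasta(a, sprintf("results/array_%s.fa", strategy), parts = TRUE)
  sizes <- rbind(sizes, data.frame(strategy = strategy,
                                   parts = nrow(a$parts), nt = a$length))
}
print(sizes)
write.table(sizes, "results/array_sizes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("tRNA-fusion cassette saves %d nt over separate units",
                sizes$nt[sizes$strategy == "msgRNA"] -
                  sizes$nt[sizes$strategy == "mtRNA"]))
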