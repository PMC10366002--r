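#!/usr/bin/env Rscript

# Step 1: simulate the study substrate -- an AT-rich circular bacterial
# chromosome with non-overlapping CDSs on both strands -- and plant ground
# truth into it: STOP-capable protospacers (sense and antisense), spacer
# off-target sites of known mismatch/bulge distance, and SNPs at known
# distances from those sites. Everything downstream (02-04) reads the
# files written here.

library(bestop)

seed <- 20231L
dir.create("results", showWarnings = FALSE)

spec <- synthetic_genome_spec(n_genes = 40L, gene_length_mean = 900,
                              gene_length_sd = 250, gc = 0.31)
res <- generate_annotated_genome(spec, seed = seed)
genome <- res$genome
ledger <- res$ledger
message(sprintf("simulated %s: %d bp, %d CDS",
                genome$id, nchar(genome$sequence), nrow(genome$features)))

# plant protospacers: clean single-C sense sites and multi-C antisense
# (coding TGG) sites, alternating
proto_entries <- list()
for (i in 1:8) {
  pl <- plant_stop_protospacer(genome, sprintf("SYN_%04d", i),
                               if (i %% 2) "sense" else "antisense", -18L)
  genome <- pl$genome
  proto_entries[[i]] <- pl$entry
}
ledger$protospacers <- do.call(rbind, proto_entries)

# plant off-target sites of one spacer at increasing distances
withr::with_seed(seed, {
  spacer <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  off_entries <- list()
  for (pr in list(c(0, "none", 0), c(2, "none", 0), c(4, "none", 0),
                  c(1, "DNA", 1), c(1, "RNA", 1))) {
    pl <- plant_offtarget_site(genome, spacer, as.integer(pr[1]), pr[2],
                               as.integer(pr[3]),
                               avoid = vapply(off_entries, function(e)
                                 e$genome_position, numeric(1)))
    genome <- pl$genome
    off_entries[[length(off_entries) + 1L]] <- pl$entry
  }
  ledger$offtargets <- do.call(rbind, off_entries)

  gv <- generate_variants(genome, ledger$offtargets,
                          distances = c(0L, 25L, 50L, 51L), n_background = 5L,
                          path = "results/planted_variants.vcf")
  ledger$variants <- gv$variants
})

write_genome(genome, "results/synthetic_genome.gb", format = "genbank")
write_genome(genome, "results/synthetic_genome.fa", format = "fasta+gff3",
             gff3 = "results/synthetic_genome.gff3")
write_ledger(ledger, "results/planted_ledger.json")
writeLines(ledger$offtargets$spacer[1], "results/offtarget_spacer.txt")

message("wrote results/synthetic_genome.{gb,fa,gff3}, planted_ledger.json, ",
        "planted_variants.vcf")
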