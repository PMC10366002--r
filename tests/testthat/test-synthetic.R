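test_that("generation is deterministic and respects the spec", {
  spec <- synthetic_genome_spec(n_genes = 12, gene_length_mean = 450,
                                gene_length_sd = 90)
  a <- generate_annotated_genome(spec, seed = 3)
  b <- generate_annotated_genome(spec, seed = 3)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$genome$features, b$genome$features)
  expect_false(identical(a$genome$sequence,
                         generate_annotated_genome(spec, seed = 4)$genome$sequence))
  # written files are byte-identical too
  f1 <- withr::local_tempfile(fileext = ".gb")
  f2 <- withr::local_tempfile(fileext = ".gb")
  write_genome(a$genome, f1); write_genome(b$genome, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_equal(nrow(a$genome$features), 12L)
  expect_true(a$genome$circular)
  expect_setequal(a$ledger$genes$id, a$genome$features$id)
})

test_that("every generated CDS is a clean open reading frame", {
  g <- generate_annotated_genome(
    synthetic_genome_spec(n_genes = 50, gene_length_mean = 300,
                          gene_length_sd = 60), seed = 9)$genome
  cds <- extract_cds_records(g)
  expect_equal(nrow(cds), 50L)
  for (i in seq_len(nrow(cds))) {
    cc <- cds$coding_sequence[i]
    expect_equal(nchar(cc) %% 3, 0)
    expect_equal(substr(cc, 1, 3), "ATG")
    codons <- substring(cc, seq(1, nchar(cc) - 2, 3), seq(3, nchar(cc), 3))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
  # non-overlapping features
  expect_true(all(diff(g$features$start) > 0))
  expect_true(all(utils::head(g$features$end, -1) <
                    utils::tail(g$features$start, -1)))
  # zero genes is allowed
  g0 <- generate_annotated_genome(synthetic_genome_spec(n_genes = 0), seed = 1)
  expect_equal(nrow(g0$genome$features), 0L)
})

test_that("extracted CDS records equal the generator ledger", {
  res <- generate_annotated_genome(
    synthetic_genome_spec(n_genes = 20, gene_length_mean = 240,
                          gene_length_sd = 30), seed = 21)
  cds <- extract_cds_records(res$genome)
  expect_equal(cds[c("id", "start", "end", "strand")],
               res$ledger$genes[c("id", "start", "end", "strand")])
})

test_that("planted sense protospacers are recovered with all attributes", {
  res <- generate_annotated_genome(
    synthetic_genome_spec(n_genes = 8, gene_length_mean = 450,
                          gene_length_sd = 60, circular = FALSE), seed = 33)
  g <- res$genome
  entries <- list()
  for (spec in list(list(id = "SYN_0001", o = -18L), list(id = "SYN_0002", o = -19L),
                    list(id = "SYN_0003", o = -17L), list(id = "SYN_0004", o = -16L))) {
    pl <- plant_stop_protospacer(g, spec$id, "sense", spec$o)
    g <- pl$genome; entries[[length(entries) + 1L]] <- pl$entry
  }
  planted <- do.call(rbind, entries)
  hits <- design_knockouts(g, pam_spec("NGG"))
  for (i in seq_len(nrow(planted))) {
    row <- hits[hits$cds_id == planted$cds_id[i] &
                  hits$genome_start == planted$genome_start[i] &
                  hits$protospacer_strand == planted$strand[i], ]
    expect_equal(nrow(row), 1L, info = planted$cds_id[i])
    expect_equal(row$orientation, "sense")
    expect_equal(row$window_c_offsets, planted$window_offsets[i])
    expect_equal(row$wt_codon, "CAA")
    expect_equal(row$mutant_codon, "TAA")
    expect_equal(row$quality, planted$quality[i])
    expect_equal(row$cds_fraction, planted$cds_fraction[i])
  }
  # the CDS length never changes and the frame stays clean
  cds <- extract_cds_records(g)
  for (cc in cds$coding_sequence) {
    codons <- substring(cc, seq(1, nchar(cc) - 2, 3), seq(3, nchar(cc), 3))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("planted antisense protospacers give the three-subset TGG edits", {
  res <- generate_annotated_genome(
    synthetic_genome_spec(n_genes = 6, gene_length_mean = 450,
                          gene_length_sd = 50, circular = FALSE), seed = 35)
  g <- res$genome
  pl <- plant_stop_protospacer(g, "SYN_0002", "antisense", -18L)
  g <- pl$genome
  hits <- design_knockouts(g, pam_spec("NGG"))
  row_i <- which(hits$cds_id == "SYN_0002" &
                   hits$genome_start == pl$entry$genome_start)
  expect_equal(length(row_i), 1L)
  row <- hits[row_i, ]
  expect_equal(row$orientation, "antisense")
  expect_equal(row$protospacer_strand, pl$entry$strand)
  expect_equal(row$quality, "multi_C")
  expect_equal(row$n_stop_edits, 3L)
  ed <- attr(hits, "stop_edits")[[row_i]]
  expect_setequal(ed$mutant_codon, c("TAA", "TAG", "TGA"))
  expect_true(all(ed$wt_codon == "TGG"))
})

test_that("planting beyond the leading-fraction boundary excludes the hit", {
  g <- quiet_genome(4, codons = 80)
  pl <- plant_stop_protospacer(g, "Q_001", "sense", -18L, at_fraction = 0.85)
  g2 <- pl$genome
  expect_gt(pl$entry$cds_fraction, 0.75)
  expect_equal(nrow(design_knockouts(g2, pam_spec("NGG"))), 0L)
  expect_equal(nrow(design_knockouts(g2, pam_spec("NGG"), first_fraction = 1)), 1L)
})

test_that("planted protospacer recovery is complete on a full synthetic run", {
  res <- generate_annotated_genome(
    synthetic_genome_spec(n_genes = 10, gene_length_mean = 360,
                          gene_length_sd = 45), seed = 55)
  g <- res$genome
  ids <- sprintf("SYN_%04d", 1:6)
  oris <- rep(c("sense", "antisense"), 3)
  entries <- list()
  for (i in seq_along(ids)) {
    pl <- plant_stop_protospacer(g, ids[i], oris[i], -18L)
    g <- pl$genome; entries[[i]] <- pl$entry
  }
  planted <- do.call(rbind, entries)
  hits <- design_knockouts(g, pam_spec("NGG"))
  keys <- paste(hits$cds_id, hits$genome_start, hits$protospacer_strand)
  want <- paste(planted$cds_id, planted$genome_start, planted$strand)
  expect_true(all(want %in% keys))  # 100% planted-feature recall
})

test_that("planted off-target retries produce the exact requested profile", {
  g <- generate_annotated_genome(
    synthetic_genome_spec(n_genes = 6, gene_length_mean = 240,
                          gene_length_sd = 30, circular = FALSE), seed = 61)$genome
  sp <- "GACCATTGCGTAACGGATTC"
  withr::with_seed(7, {
    for (prof in list(c(0, 0), c(1, 0), c(3, 0))) {
      pl <- plant_offtarget_site(g, sp, prof[1], "none")
      q <- offtarget_query("t", sp, "NGG", prof[1], 0, 0)
      found <- search_offtargets(pl$genome, q)
      r <- found[found$genome_position == pl$entry$genome_position, ]
      expect_equal(r$mismatches, prof[1])
    }
    pd <- plant_offtarget_site(g, sp, 1, "DNA", 1)
    fd <- search_offtargets(pd$genome, offtarget_query("t", sp, "NGG", 1, 1, 0))
    rd <- fd[fd$genome_position == pd$entry$genome_position, ]
    expect_equal(rd$bulge_type, "DNA")
    expect_equal(rd$bulge_size, 1L)
  })
})

test_that("variant planting hits the association boundary exactly", {
  g <- quiet_genome(4)
  sites <- data.frame(genome_position = 300L, genome_end = 319L)
  withr::with_seed(13, {
    gv <- generate_variants(g, sites, distances = c(50L, 51L),
                            n_background = 3L)
  })
  v <- gv$variants
  expect_true(v$expect_associated[v$distance == 50 & !is.na(v$distance)])
  expect_false(v$expect_associated[v$distance == 51 & !is.na(v$distance)])
  # background variants sit far from the site and are never associated
  bg <- v[is.na(v$distance), ]
  expect_equal(nrow(bg), 3L)
  expect_true(all(pmax(300L - bg$pos, bg$pos - 319L) > 200L))
})

test_that("an end-to-end synthetic off-target report matches its ledger", {
  res <- generate_annotated_genome(
    synthetic_genome_spec(n_genes = 8, gene_length_mean = 300,
                          gene_length_sd = 40, circular = FALSE), seed = 71)
  g <- res$genome
  sp <- "CTAGGTACCGATTGCAAGGT"
  withr::with_seed(19, {
    p1 <- plant_offtarget_site(g, sp, 2, "none"); g <- p1$genome
    p2 <- plant_offtarget_site(g, sp, 1, "RNA", 1,
                               avoid = p1$entry$genome_position)
    g <- p2$genome
    ledger <- rbind(p1$entry, p2$entry)
    vcf <- withr::local_tempfile(fileext = ".vcf")
    gv <- generate_variants(g, ledger, distances = c(10L, 51L),
                            n_background = 3L, path = vcf)
  })
  sites <- search_offtargets(g, offtarget_query("sp", sp, "NGG", 2, 0, 1))
  # every ledger site is recovered with its stored profile
  for (i in 1:2) {
    r <- sites[sites$genome_position == ledger$genome_position[i], ]
    expect_equal(nrow(r), 1L)
    expect_equal(r$mismatches, ledger$mismatches[i])
    expect_equal(r$bulge_type, ledger$bulge_type[i])
  }
  assoc <- associate_variants(sites, read_variants(gv$path))
  v <- gv$variants
  expect_setequal(assoc$pos, v$pos[v$expect_associated])
})

test_that("ledger JSON serialisation is lossless for coordinates", {
  res <- generate_annotated_genome(synthetic_genome_spec(n_genes = 5), seed = 81)
  js <- withr::local_tempfile(fileext = ".json")
  write_ledger(res$ledger, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$genes$start, res$ledger$genes$start)
  expect_equal(back$genes$id, res$ledger$genes$id)
})
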