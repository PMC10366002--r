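test_that("query variant expansion matches exhaustive enumeration", {
  sp <- "ACGTACGTACGTACGTACGT"
  q0 <- offtarget_query("q", sp, max_mismatches = 3, max_dna_bulge = 0,
                        max_rna_bulge = 0)
  v0 <- generate_query_variants(q0)
  expect_equal(nrow(v0), 1L)
  expect_equal(v0$pattern, sp)

  # 1-nt RNA bulge: distinct 19-mers from deleting one interior position
  q1 <- offtarget_query("q", sp, max_rna_bulge = 1, max_dna_bulge = 0)
  v1 <- generate_query_variants(q1)
  ch <- strsplit(sp, "")[[1]]
  dels <- unique(vapply(2:19, function(i) paste(ch[-i], collapse = ""),
                        character(1)))
  expect_setequal(v1$pattern[v1$bulge_type == "RNA"], dels)

  # repeated bases collapse deletion variants
  rep_sp <- "AAAAAAAAAACGTACGTACG"
  qr <- offtarget_query("q", rep_sp, max_rna_bulge = 1, max_dna_bulge = 0)
  vr <- generate_query_variants(qr)
  chr <- strsplit(rep_sp, "")[[1]]
  delr <- unique(vapply(2:19, function(i) paste(chr[-i], collapse = ""),
                        character(1)))
  expect_equal(sum(vr$bulge_type == "RNA"), length(delr))
  expect_lt(length(delr), 18L)

  # DNA bulges insert N runs at interior junctions only
  q2 <- offtarget_query("q", sp, max_dna_bulge = 2, max_rna_bulge = 0)
  v2 <- generate_query_variants(q2)
  dna <- v2[v2$bulge_type == "DNA", ]
  expect_equal(nrow(dna), 19L + 19L)   # sizes 1 and 2, junctions 1..19
  expect_true(all(!startsWith(dna$pattern, "N")))
  expect_true(all(!endsWith(dna$pattern, "N")))
})

test_that("exact search (all limits 0) equals naive string matching", {
  g <- small_genome(201, n_genes = 4)
  # take a real substring as the spacer so at least one site exists
  sp <- substr(g$sequence, 301, 320)
  pamseq <- substr(g$sequence, 321, 323)
  skip_chars <- grepl("[^ACGT]", sp)
  q <- offtarget_query("exact", sp, pam_pattern = "NNN", max_mismatches = 0,
                       max_dna_bulge = 0, max_rna_bulge = 0)
  got <- search_offtargets(g, q)
  # naive: all occurrences of the spacer or its reverse complement
  naive_plus <- gregexpr(sp, g$sequence, fixed = TRUE)[[1]]
  naive_minus <- gregexpr(revcomp(sp), g$sequence, fixed = TRUE)[[1]]
  naive <- c(naive_plus[naive_plus > 0], naive_minus[naive_minus > 0])
  # search requires 3 nt of PAM room; drop naive sites at the very ends
  naive <- naive[naive + 22 <= nchar(g$sequence) & naive >= 4]
  expect_setequal(got$genome_position, naive)
  expect_true(301 %in% got$genome_position)
  expect_true(all(got$mismatches == 0))
})

test_that("planted mismatch/bulge sites are found exactly at their limits", {
  g <- generate_annotated_genome(
    synthetic_genome_spec(n_genes = 6, gene_length_mean = 300,
                          gene_length_sd = 50, intergenic_mean = 150,
                          intergenic_sd = 20, circular = FALSE), seed = 5)$genome
  sp <- "ACGTTGCAGATCCGTTAGGA"
  withr::with_seed(99, {
    p0 <- plant_offtarget_site(g, sp, 0, "none")
    g <- p0$genome
    p2 <- plant_offtarget_site(g, sp, 2, "none",
                               avoid = p0$entry$genome_position)
    g <- p2$genome
    pr <- plant_offtarget_site(g, sp, 2, "RNA", 1,
                               avoid = c(p0$entry$genome_position,
                                         p2$entry$genome_position))
    g <- pr$genome
  })

  # verbatim site at limits (0,0,0)
  q0 <- offtarget_query("sp", sp, "NGG", 0, 0, 0)
  s0 <- search_offtargets(g, q0)
  expect_equal(s0$genome_position, p0$entry$genome_position)
  expect_equal(s0$mismatches, 0L)

  # 2-mismatch site present at (2,0,0), absent at (1,0,0)
  s2 <- search_offtargets(g, offtarget_query("sp", sp, "NGG", 2, 0, 0))
  expect_true(p2$entry$genome_position %in% s2$genome_position)
  r2 <- s2[s2$genome_position == p2$entry$genome_position, ]
  expect_equal(r2$mismatches, 2L)
  s1 <- search_offtargets(g, offtarget_query("sp", sp, "NGG", 1, 0, 0))
  expect_false(p2$entry$genome_position %in% s1$genome_position)

  # RNA-bulge site found at (2,0,1) with its profile, absent at (1,0,1)
  sr <- search_offtargets(g, offtarget_query("sp", sp, "NGG", 2, 0, 1))
  rr <- sr[sr$genome_position == pr$entry$genome_position, ]
  expect_equal(nrow(rr), 1L)
  expect_equal(rr$mismatches, 2L)
  expect_equal(rr$bulge_type, "RNA")
  expect_equal(rr$bulge_size, 1L)
  sr1 <- search_offtargets(g, offtarget_query("sp", sp, "NGG", 1, 0, 1))
  expect_false(pr$entry$genome_position %in% sr1$genome_position)
})

test_that("search equals the exhaustive oracle and is monotone in limits", {
  g <- small_genome(211, n_genes = 3, mean_len = 300)
  sp <- substr(g$sequence, 401, 420)  # near-real spacer: plenty of hits
  lims <- list(c(3, 1, 1), c(2, 1, 1), c(3, 0, 0))
  prev <- NULL
  for (lm in lims) {
    q <- offtarget_query("sp", sp, "NG", lm[1], lm[2], lm[3])
    got <- search_offtargets(g, q, mode = "raw")
    keys <- unique(paste(got$genome_position, got$strand, got$mismatches,
                         got$bulge_type, got$bulge_size))
    ref <- oracle_offtarget(g, sp, "NG", lm[1], lm[2], lm[3])
    ref_keys <- unique(paste(ref$pos, ref$strand, ref$mm, ref$type, ref$size))
    expect_setequal(keys, ref_keys)
  }
  # monotone: loosening any limit can only add (position, strand) sites
  base <- search_offtargets(g, offtarget_query("sp", sp, "NG", 2, 0, 0))
  wider <- search_offtargets(g, offtarget_query("sp", sp, "NG", 3, 1, 1))
  expect_true(all(paste(base$genome_position, base$strand) %in%
                    paste(wider$genome_position, wider$strand)))
})

test_that("reported sites re-validate from their aligned strings", {
  g <- small_genome(221, n_genes = 3)
  sp <- substr(g$sequence, 150, 169)
  got <- search_offtargets(g, offtarget_query("sp", sp, "NN", 3, 1, 1),
                           mode = "raw")
  expect_gt(nrow(got), 0)
  for (i in seq_len(nrow(got))) {
    at <- strsplit(got$aligned_target[i], "")[[1]]
    aq <- strsplit(got$aligned_query[i], "")[[1]]
    expect_equal(length(at), length(aq))
    # removing target gaps recovers the genomic substring
    tgt <- paste(at[at != "-"], collapse = "")
    sub <- substr(g$sequence, got$genome_position[i], got$genome_end[i])
    if (got$strand[i] == "-") sub <- revcomp(sub)
    expect_equal(tgt, sub)
    # recomputing mismatches over aligned non-gap columns matches the record
    cmp <- at != aq & at != "-" & aq != "-"
    expect_equal(sum(cmp), got$mismatches[i])
  }
})

test_that("variant association distance rule is inclusive at the threshold", {
  g <- quiet_genome(4)
  sites <- data.frame(query_label = "q", genome_position = 500L,
                      genome_end = 519L, strand = "+", mismatches = 0L,
                      bulge_type = "none", bulge_size = 0L)
  mkvar <- function(pos) data.frame(chrom = "QUIET", pos = pos, ref = "A",
                                    alt = "T")
  expect_equal(associate_variants(sites, mkvar(510))$distance, 0L)   # inside
  expect_equal(associate_variants(sites, mkvar(569))$distance, 50L)  # at limit
  expect_equal(nrow(associate_variants(sites, mkvar(570))), 0L)      # limit+1
  expect_equal(associate_variants(sites, mkvar(450))$distance, 50L)  # upstream
})

test_that("generated variant files round-trip and associate per the ledger", {
  g <- generate_annotated_genome(
    synthetic_genome_spec(n_genes = 5, gene_length_mean = 300,
                          gene_length_sd = 40, intergenic_mean = 120,
                          intergenic_sd = 10, circular = FALSE), seed = 17)$genome
  sp <- "TTACGGATCAGGCATTACCG"
  withr::with_seed(31, {
    pl <- plant_offtarget_site(g, sp, 1, "none")
    g <- pl$genome
    vcf <- withr::local_tempfile(fileext = ".vcf")
    gv <- generate_variants(g, pl$entry, distances = c(0L, 50L, 51L),
                            n_background = 4L, path = vcf)
    vars <- read_variants(vcf)
    expect_equal(nrow(vars), nrow(gv$variants))
    expect_equal(vars$pos, gv$variants$pos)
    # ref alleles match the genome
    expect_equal(vars$ref, vapply(vars$pos, function(p)
      substr(g$sequence, p, p), character(1)))

    sites <- search_offtargets(g, offtarget_query("sp", sp, "NGG", 1, 0, 0))
    assoc <- associate_variants(sites, vars)
    expect_setequal(assoc$pos,
                    gv$variants$pos[gv$variants$expect_associated])
  })
})

test_that("local alignment fallback finds verbatim spacers and obeys its oracle", {
  ctx <- paste0(strrep("T", 11), "ACGGATTACAGGCCTTAAGC", strrep("T", 10))
  rep1 <- local_align_fallback("ACGGATTACAGGCCTTAAGC", ctx)
  expect_equal(rep1$matches, 20L)
  expect_equal(rep1$mismatches, 0L)
  expect_equal(rep1$gaps, 0L)
  expect_true(rep1$reported)
  expect_equal(rep1$context_start, 12L)

  # reverse-complement occurrences are found in the other orientation
  rep2 <- local_align_fallback(revcomp("ACGGATTACAGGCCTTAAGC"), ctx)
  expect_equal(rep2$orientation, "-")
  expect_equal(rep2$matches, 20L)

  # random spacer/context pairs: score equals a hand-rolled Smith-Waterman
  withr::with_seed(77, {
    for (i in 1:5) {
      sp <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
      cx <- paste(sample(c("A", "C", "G", "T"), 41, TRUE), collapse = "")
      got <- local_align_fallback(sp, cx)
      ref <- max(oracle_sw_score(sp, cx), oracle_sw_score(revcomp(sp), cx))
      expect_equal(got$score, ref)
    }
  })
  expect_error(local_align_fallback("ACGTACGTACGTACGTACGTA", "ACGT"),
               "shorter")
})

test_that("variant context extraction is centred and wrap-aware", {
  g <- annotated_genome("c", strrep("ACGT", 30), circular = TRUE)
  ctx <- variant_context(g, 25)
  expect_equal(nchar(ctx), 41L)
  expect_equal(substr(ctx, 21, 21), substr(g$sequence, 25, 25))
  # near the origin the context wraps on a circular genome
  expect_equal(nchar(variant_context(g, 5)), 41L)
  g_lin <- annotated_genome("l", strrep("ACGT", 30), circular = FALSE)
  expect_error(variant_context(g_lin, 5))
})

test_that("region-restricted search only reports sites inside the region", {
  g <- small_genome(231, n_genes = 3)
  sp <- substr(g$sequence, 500, 519)
  q <- offtarget_query("sp", sp, "NN", 3, 0, 0)
  all_sites <- search_offtargets(g, q)
  reg <- c(400L, 700L)
  reg_sites <- search_offtargets(g, q, region = reg)
  expect_true(all(reg_sites$genome_position >= reg[1] &
                    reg_sites$genome_end <= reg[2]))
  inside <- all_sites[all_sites$genome_position >= reg[1] &
                        all_sites$genome_end + 3 <= reg[2], ]
  expect_true(all(inside$genome_position %in% reg_sites$genome_position))
})
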