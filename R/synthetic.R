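#' Specification of a synthetic annotated genome
#'
#' Describes the random genome the generator emits: a circular prokaryotic
#' replicon with non-overlapping, internally-stop-free CDSs on both
#' strands separated by intergenic spacers. Defaults emulate a small,
#' AT-rich acetogen chromosome.
#'
#' @param n_genes number of CDSs.
#' @param gene_length_mean,gene_length_sd gene length distribution in nt
#'   (rounded to a multiple of 3, minimum 30 nt).
#' @param intergenic_mean,intergenic_sd intergenic length distribution
#'   (minimum 30 nt so planted features clear CDS boundaries).
#' @param gc GC content of intergenic and coding background.
#' @param circular circular topology flag.
#' @param minus_fraction proportion of genes placed on the minus strand.
#' @return a `synthetic_genome_spec` object.
#' @export
synthetic_genome_spec <- function(n_genes = 50L, gene_length_mean = 900,
                                  gene_length_sd = 250,
                                  intergenic_mean = 120, intergenic_sd = 60,
                                  gc = 0.31, circular = TRUE,
                                  minus_fraction = 0.5) {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (gene_length_mean <= 0 || intergenic_mean <= 0) stop("lengths must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_mean = gene_length_mean,
                 gene_length_sd = gene_length_sd,
                 intergenic_mean = intergenic_mean,
                 intergenic_sd = intergenic_sd,
                 gc = gc, circular = circular,
                 minus_fraction = minus_fraction),
            class = "synthetic_genome_spec")
}

# One random codon that is not a stop, bases i.i.d. at the spec GC.
random_codons <- function(n, gc) {
  if (n <= 0L) return(character(0))
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- vapply(need, function(i) random_dna(3L, gc), character(1))
    ok <- !(cand %in% STOP_CODONS)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic annotated genome with ground truth
#'
#' Emits a genome whose every CDS starts with ATG, ends with a stop codon,
#' contains no internal in-frame stop, and does not overlap its
#' neighbours; byte-identical output for identical spec and seed.
#'
#' @param spec a [synthetic_genome_spec()].
#' @param seed integer seed.
#' @param id replicon id.
#' @return list with `genome` (an [annotated_genome()]) and `ledger` (a
#'   [planted_ledger()] whose `genes` table records every CDS).
#' @export
generate_annotated_genome <- function(spec = synthetic_genome_spec(), seed,
                                      id = "SYNB01") {
  withr::with_seed(seed, {
    pieces <- character(0)
    feats <- list()
    pos <- 1L
    for (g in seq_len(spec$n_genes)) {
      ig <- max(30L, as.integer(round(stats::rnorm(1, spec$intergenic_mean,
                                                   spec$intergenic_sd))))
      pieces <- c(pieces, random_dna(ig, spec$gc))
      pos <- pos + ig
      len <- as.integer(round(stats::rnorm(1, spec$gene_length_mean,
                                           spec$gene_length_sd)))
      len <- max(30L, 3L * as.integer(round(len / 3)))
      n_internal <- len %/% 3L - 2L
      coding <- paste0("ATG", paste(random_codons(n_internal, spec$gc), collapse = ""),
                       sample(STOP_CODONS, 1L))
      strand <- if (stats::runif(1) < spec$minus_fraction) "-" else "+"
      genomic <- if (strand == "+") coding else revcomp(coding)
      pieces <- c(pieces, genomic)
      feats[[g]] <- data.frame(id = sprintf("SYN_%04d", g), start = pos,
                               end = pos + len - 1L, strand = strand,
                               pseudo = FALSE, stringsAsFactors = FALSE)
      pos <- pos + len
    }
    ig <- max(30L, as.integer(round(stats::rnorm(1, spec$intergenic_mean,
                                                 spec$intergenic_sd))))
    pieces <- c(pieces, random_dna(ig, spec$gc))
    genome <- annotated_genome(id, paste(pieces, collapse = ""),
                               if (length(feats)) do.call(rbind, feats) else NULL,
                               circular = spec$circular)
    list(genome = genome, ledger = planted_ledger(genes = genome$features))
  })
}

#' Planted-feature ledger
#'
#' Ground-truth record of everything the synthetic generator embedded in a
#' genome, enabling exact recovery tests.
#'
#' @param genes,protospacers,offtargets,variants component data frames.
#' @return a `planted_ledger` list.
#' @export
planted_ledger <- function(genes = NULL, protospacers = NULL,
                           offtargets = NULL, variants = NULL) {
  structure(list(genes = genes, protospacers = protospacers,
                 offtargets = offtargets, variants = variants),
            class = "planted_ledger")
}

#' Write a ledger to JSON
#' @param ledger a [planted_ledger()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  jsonlite::write_json(unclass(ledger), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# Replace coding positions [p1, p2] of a CDS with `replacement`
# (coding-strand sequence), editing the genome in place.
splice_coding <- function(genome, feat, p1, p2, replacement) {
  stopifnot(nchar(replacement) == p2 - p1 + 1L)
  if (feat$strand == "+") {
    g1 <- feat$start + p1 - 1L; g2 <- feat$start + p2 - 1L
    piece <- replacement
  } else {
    g1 <- feat$end - p2 + 1L; g2 <- feat$end - p1 + 1L
    piece <- revcomp(replacement)
  }
  substr(genome$sequence, g1, g2) <- piece
  genome
}

# Genomic interval of coding positions [p1, p2].
coding_to_genomic <- function(feat, p1, p2) {
  if (feat$strand == "+") c(feat$start + p1 - 1L, feat$start + p2 - 1L)
  else c(feat$end - p2 + 1L, feat$end - p1 + 1L)
}

#' Plant a STOP-capable protospacer into a CDS
#'
#' Rewrites a codon-aligned region of the chosen CDS so that a
#' protospacer + NGG PAM exists whose editing-window C->T conversion
#' produces a premature stop, without breaking the reading frame or
#' introducing an internal stop. Sense planting embeds a CAA codon with
#' its single window C at `window_offset` (expected edit CAA->TAA, quality
#' `clean` at -18/-19); antisense planting embeds a coding-strand TGG whose
#' two protospacer-strand Cs sit at `window_offset` and `window_offset+1`
#' (three stop-producing subsets, quality `multi_C`).
#'
#' @param genome an [annotated_genome()].
#' @param cds_id locus tag of the target CDS.
#' @param orientation `"sense"` or `"antisense"` (protospacer strand
#'   relative to the coding strand).
#' @param window_offset PAM-relative offset of the (first) planted C.
#' @param at_fraction where in the CDS to place the stop codon (fraction
#'   of CDS length; default 0.3; values > 0.75 plant beyond the default
#'   design threshold).
#' @param window an [editing_window()] (bounds checked).
#' @return list with `genome` (edited) and `entry` (one-row ledger
#'   data.frame: expected hit coordinates, strand, codons, quality).
#' @export
plant_stop_protospacer <- function(genome, cds_id,
                                   orientation = c("sense", "antisense"),
                                   window_offset = -18L, at_fraction = 0.3,
                                   window = editing_window()) {
  orientation <- match.arg(orientation)
  o <- as.integer(window_offset)
  if (orientation == "sense") {
    if (o < window$from_pos || o > window$to_pos) stop("offset outside window")
  } else {
    if (o < window$from_pos || o + 1L > window$to_pos) {
      stop("antisense planting needs offsets ", o, " and ", o + 1L, " inside the window")
    }
  }
  fi <- match(cds_id, genome$features$id)
  if (is.na(fi)) stop("no such CDS: ", cds_id)
  feat <- genome$features[fi, ]
  len <- feature_span(feat$start, feat$end, genome_length(genome))

  if (orientation == "sense") {
    i <- 21L + o                           # protospacer index of the C
    # stop codon start c1 (codon aligned), protospacer at [p1, p1+19]
    k <- max(2L, as.integer(round(at_fraction * len / 3)))
    c1 <- 3L * k + 1L
    p1 <- c1 - (i - 1L)
    pam_end <- p1 + 22L
    if (p1 < 4L || pam_end > len - 3L) {
      stop("no valid placement for the protospacer in ", cds_id)
    }
    # codon-aligned rewrite: [r1, r2] covers protospacer + PAM + 19 nt
    # 3' buffer (keeps the planted C out of any other PAM's window)
    r1 <- p1 - (p1 - 1L) %% 3L
    r2e <- pam_end + 19L
    r2 <- r2e + (3L - r2e %% 3L) %% 3L
    r2 <- min(r2, len - 3L)
    region <- rep("A", r2 - r1 + 1L)
    region[(p1 - r1 + 1L) + i - 1L] <- "C"          # the editable C (of CAA)
    region[(pam_end - r1 + 1L) - 1L:0L] <- "G"      # AGG PAM (A is default)
    genome <- splice_coding(genome, feat, r1, r2, paste(region, collapse = ""))
    gp <- coding_to_genomic(feat, p1, p1 + 19L)
    entry <- data.frame(
      kind = "protospacer", cds_id = cds_id, orientation = "sense",
      window_offsets = as.character(o),
      genome_start = gp[1], genome_end = gp[2],
      strand = feat$strand,
      wt_codon = "CAA", stop_triplet = "TAA",
      cds_fraction = c1 / len, quality = classify_quality(o),
      n_stop_subsets = 1L, stringsAsFactors = FALSE)
  } else {
    # coding TGG at c1, anti-strand PAM (coding CCT) at [a-3, a-1],
    # protospacer (anti strand) over coding [a, a+19]
    k <- max(3L, as.integer(round(at_fraction * len / 3)))
    c1 <- 3L * k + 1L
    a <- c1 + 3L + o
    if (a - 3L < 4L || a + 19L > len - 3L) {
      stop("no valid placement for the protospacer in ", cds_id)
    }
    r1 <- (a - 3L) - (a - 3L - 1L) %% 3L
    r1 <- max(4L, r1 - 18L)               # 5' buffer on the coding strand
    r1 <- r1 - (r1 - 1L) %% 3L
    if (r1 < 4L) r1 <- r1 + 3L
    r2 <- a + 19L
    r2 <- r2 + (3L - r2 %% 3L) %% 3L
    r2 <- min(r2, len - 3L)
    region <- rep("A", r2 - r1 + 1L)
    at <- function(p) p - r1 + 1L
    region[at(a):at(r2)] <- "T"           # coding image of an all-A anti spacer
    region[at(a - 3L):at(a - 1L)] <- c("C", "C", "T")   # anti-strand AGG PAM
    region[at(c1):at(c1 + 2L)] <- c("T", "G", "G")      # the target codon
    genome <- splice_coding(genome, feat, r1, r2, paste(region, collapse = ""))
    gp <- coding_to_genomic(feat, a, a + 19L)
    entry <- data.frame(
      kind = "protospacer", cds_id = cds_id, orientation = "antisense",
      window_offsets = paste(c(o, o + 1L), collapse = ","),
      genome_start = gp[1], genome_end = gp[2],
      strand = if (feat$strand == "+") "-" else "+",
      wt_codon = "TGG", stop_triplet = "TAA",
      cds_fraction = c1 / len, quality = "multi_C",
      n_stop_subsets = 3L, stringsAsFactors = FALSE)
  }
  list(genome = genome, entry = entry)
}

# Intergenic intervals with `clearance` nt kept clear of every feature.
intergenic_intervals <- function(genome, clearance = 25L) {
  n <- genome_length(genome)
  ft <- genome$features
  if (nrow(ft) == 0L) return(data.frame(start = 1L, end = n))
  occ <- IRanges::reduce(IRanges::IRanges(pmax(ft$start - clearance, 1L),
                                          pmin(ft$end + clearance, n)))
  gaps <- IRanges::gaps(occ, start = 1L, end = n)
  data.frame(start = IRanges::start(gaps), end = IRanges::end(gaps))
}

# Mutate `n` positions of `target` (not inside `protect` positions),
# each to a different random base.
apply_mismatches <- function(target, n, protect = integer(0)) {
  ch <- seq_chars(target)
  avail <- setdiff(seq_along(ch), protect)
  pos <- sort(sample(avail, n))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  list(seq = paste(ch, collapse = ""), positions = pos)
}

#' Plant an off-target site of known distance into intergenic space
#'
#' Writes a target sequence whose best gapped alignment to the spacer has
#' exactly the requested mismatch count and bulge profile, followed by a
#' valid PAM, at a randomly chosen intergenic position (>= 25 nt clear of
#' any CDS). The planted locus is re-verified by exhaustive search; if a
#' closer match arises by chance the construction is retried (up to
#' `retries` times) before failing.
#'
#' @param genome an [annotated_genome()].
#' @param spacer spacer sequence the site should resemble.
#' @param n_mismatches requested mismatch count.
#' @param bulge_type `"none"`, `"DNA"` or `"RNA"`.
#' @param bulge_size bulge length (0 when `bulge_type = "none"`).
#' @param pam PAM to write 3' of the target (default `"AGG"`, an NGG PAM).
#' @param strand strand to plant on.
#' @param avoid integer positions (forward coords) to keep >= 60 nt away
#'   from (earlier planted sites).
#' @param retries rejection-sampling budget.
#' @return list with `genome` (edited) and `entry` (ledger row:
#'   `genome_position`, `genome_end`, `strand`, `mismatches`,
#'   `bulge_type`, `bulge_size`, `target_seq`).
#' @export
plant_offtarget_site <- function(genome, spacer, n_mismatches = 0L,
                                 bulge_type = c("none", "DNA", "RNA"),
                                 bulge_size = 0L, pam = "AGG", strand = "+",
                                 avoid = integer(0), retries = 100L) {
  bulge_type <- match.arg(bulge_type)
  if (bulge_type == "none") bulge_size <- 0L
  if (bulge_type != "none" && bulge_size < 1L) stop("bulge_size must be >= 1")
  spacer <- toupper(spacer)
  L <- nchar(spacer)
  gaps <- intergenic_intervals(genome)

  for (try in seq_len(retries)) {
    # build the target from the spacer
    base <- spacer
    if (bulge_type == "RNA") {
      i <- sample(2:(L - bulge_size), 1L)
      base <- paste(seq_chars(spacer)[-(i:(i + bulge_size - 1L))], collapse = "")
    } else if (bulge_type == "DNA") {
      i <- sample(1:(L - 1L), 1L)
      ins <- random_dna(bulge_size, 0.5)
      base <- paste0(substr(spacer, 1L, i), ins, substr(spacer, i + 1L, L))
    }
    mm <- apply_mismatches(base, n_mismatches)
    target <- paste0(mm$seq, pam)
    tl <- nchar(target)

    ok_gaps <- gaps[gaps$end - gaps$start + 1L >= tl, , drop = FALSE]
    if (nrow(ok_gaps) == 0L) stop("no intergenic interval can hold the site")
    gi <- ok_gaps[sample(nrow(ok_gaps), 1L), ]
    pos <- sample(gi$start:(gi$end - tl + 1L), 1L)
    if (length(avoid) && any(abs(avoid - pos) < 60L)) next

    cand <- genome
    piece <- if (strand == "+") target else revcomp(target)
    substr(cand$sequence, pos, pos + tl - 1L) <- piece

    # verify: at the planted locus the best profile is exactly as requested
    q <- offtarget_query("planted", spacer, pam_pattern = "NGG",
                         max_mismatches = n_mismatches,
                         max_dna_bulge = max(bulge_size, 2L),
                         max_rna_bulge = max(bulge_size, 2L))
    reg <- c(max(1L, pos - 5L), min(genome_length(cand), pos + tl + 5L))
    found <- search_offtargets(cand, q, mode = "primary", region = reg)
    target_start <- if (strand == "+") pos else pos + nchar(pam)
    row <- found[found$genome_position == target_start & found$strand == strand, ]
    profile_ok <- nrow(row) == 1L && row$mismatches == n_mismatches &&
      row$bulge_type == bulge_type && row$bulge_size == bulge_size
    # and nothing strictly better exists there
    if (profile_ok && n_mismatches > 0L) {
      q2 <- offtarget_query("planted", spacer, pam_pattern = "NGG",
                            max_mismatches = n_mismatches - 1L,
                            max_dna_bulge = max(bulge_size, 2L),
                            max_rna_bulge = max(bulge_size, 2L))
      closer <- search_offtargets(cand, q2, mode = "primary", region = reg)
      if (nrow(closer)) profile_ok <- FALSE
    }
    if (profile_ok) {
      entry <- data.frame(
        kind = "offtarget", spacer = spacer,
        genome_position = target_start,
        genome_end = target_start + nchar(mm$seq) - 1L,
        strand = strand, mismatches = n_mismatches,
        bulge_type = bulge_type, bulge_size = as.integer(bulge_size),
        target_seq = mm$seq, stringsAsFactors = FALSE)
      return(list(genome = cand, entry = entry))
    }
  }
  stop("could not plant an off-target site with the requested profile after ",
       retries, " attempts")
}

#' Generate SNP records at controlled distances from sites
#'
#' Emits one SNP per requested distance for each site (downstream of the
#' site end, clipped to the genome), plus background SNPs far (> 10x the
#' association threshold) from every site, and writes a minimal VCF.
#'
#' @param genome an [annotated_genome()].
#' @param sites data.frame with `genome_position`, `genome_end` (ledger
#'   entries or search results).
#' @param distances integer distances to plant for each site (0 = inside).
#' @param n_background count of background SNPs, placed more than
#'   `4 * max_distance` nt from every site.
#' @param path optional VCF output path.
#' @param max_distance association threshold the ledger annotates against.
#' @return list with `variants` (data.frame: `chrom`, `pos`, `ref`, `alt`,
#'   `site_index`, `distance`, `expect_associated`) and `path`.
#' @export
generate_variants <- function(genome, sites, distances = c(0L, 25L, 50L, 51L),
                              n_background = 5L, path = NULL,
                              max_distance = 50L) {
  n <- genome_length(genome)
  sc <- seq_chars(genome$sequence)
  mk_alt <- function(ref) sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  # a variant planted relative to one site may still fall within range of
  # another, so the expectation is evaluated against every site
  dist_any <- function(p) {
    min(pmax(sites$genome_position - p, p - sites$genome_end, 0L))
  }
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (d in distances) {
      pos <- min(n, sites$genome_end[i] + d)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = genome$id, pos = pos, ref = sc[pos], alt = mk_alt(sc[pos]),
        site_index = i, distance = d,
        expect_associated = dist_any(pos) <= max_distance,
        stringsAsFactors = FALSE)
    }
  }
  far <- function(p) all(pmax(sites$genome_position - p, p - sites$genome_end, 0L) >
                           4L * max_distance)
  placed <- 0L
  attempts <- 0L
  while (placed < n_background) {
    attempts <- attempts + 1L
    if (attempts > 1000L * max(n_background, 1L)) {
      stop("cannot place background variants > ", 4L * max_distance,
           " nt from every site on this genome")
    }
    p <- sample(n, 1L)
    if (sc[p] == "N" || !far(p)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = genome$id, pos = p, ref = sc[p], alt = mk_alt(sc[p]),
      site_index = NA_integer_, distance = NA_integer_,
      expect_associated = FALSE, stringsAsFactors = FALSE)
    placed <- placed + 1L
  }
  variants <- do.call(rbind, rows)
  variants <- variants[order(variants$pos), ]
  rownames(variants) <- NULL
  if (!is.null(path)) write_minimal_vcf(variants, genome, path)
  list(variants = variants, path = path)
}

# Minimal VCF 4.2 writer (plain text, one contig).
write_minimal_vcf <- function(variants, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", genome$id,
                       genome_length(genome)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(variants))) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t99\tPASS\t.",
                       variants$chrom[i], variants$pos[i], variants$ref[i],
                       variants$alt[i]), con)
  }
  invisible(path)
}
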