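#' Read an annotated genome
#'
#' Reads a GenBank flat file, or a FASTA plus a GFF3 annotation, into an
#' [annotated_genome()]. CDS features whose length is not a multiple of 3
#' (e.g. frameshifted pseudogenes) are kept but flagged `pseudo` and are
#' excluded from design scans; the circular flag is taken from the GenBank
#' LOCUS topology (GFF3 input is linear unless `circular = TRUE`).
#'
#' @param path path to the GenBank file, or to the FASTA when
#'   `format = "fasta+gff3"`.
#' @param format `"genbank"` or `"fasta+gff3"`.
#' @param gff3 path to the GFF3 file (required for `"fasta+gff3"`).
#' @param circular override/force the circular flag (GFF3 has no topology
#'   field).
#' @return an [annotated_genome()].
#' @export
read_genome <- function(path, format = c("genbank", "fasta+gff3"),
                        gff3 = NULL, circular = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  g <- if (format == "genbank") {
    read_genbank(path)
  } else {
    if (is.null(gff3)) stop("format 'fasta+gff3' needs the gff3= path")
    fa <- Biostrings::readDNAStringSet(path)
    if (length(fa) != 1L) stop("expected a single-sequence FASTA, got ", length(fa))
    seq_id <- sub("\\s.*$", "", names(fa)[1])
    gr <- rtracklayer::import(gff3, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    if (length(gr) && !all(as.character(GenomicRanges::seqnames(gr)) == seq_id)) {
      stop("GFF3 seqid does not match FASTA sequence id '", seq_id, "'")
    }
    ids <- gr$locus_tag %||% gr$ID %||% paste0("CDS_", seq_along(gr))
    ids[is.na(ids)] <- paste0("CDS_", which(is.na(ids)))
    ft <- if (length(gr)) data.frame(
      id = as.character(ids),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      pseudo = if (!is.null(gr$pseudo)) !is.na(gr$pseudo) else FALSE,
      stringsAsFactors = FALSE) else NULL
    annotated_genome(seq_id, as.character(fa[[1]]),
                     ft, circular = isTRUE(circular))
  }
  if (!is.null(circular)) g$circular <- circular
  # CDS length not divisible by 3 cannot carry the codon logic: flag pseudo
  if (nrow(g$features)) {
    span <- feature_span(g$features$start, g$features$end, genome_length(g))
    bad <- span %% 3L != 0L
    g$features$pseudo <- g$features$pseudo | bad
  }
  g
}

#' Write an annotated genome
#'
#' Emits either a GenBank flat file or a FASTA + GFF3 pair; both round-trip
#' through [read_genome()].
#'
#' @param genome an [annotated_genome()].
#' @param path output path (GenBank) or FASTA path.
#' @param format `"genbank"` or `"fasta+gff3"`.
#' @param gff3 GFF3 output path for `"fasta+gff3"`.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, format = c("genbank", "fasta+gff3"),
                         gff3 = NULL) {
  format <- match.arg(format)
  if (format == "genbank") return(invisible(write_genbank(genome, path)))
  if (is.null(gff3)) stop("format 'fasta+gff3' needs the gff3= path")
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path)
  ft <- genome$features
  if (nrow(ft)) {
    gr <- GenomicRanges::GRanges(
      seqnames = genome$id,
      ranges = IRanges::IRanges(start = ft$start, end = ft$end),
      strand = ft$strand)
    gr$type <- "CDS"
    gr$ID <- ft$id
    gr$locus_tag <- ft$id
    gr$phase <- 0L
    if (any(ft$pseudo)) gr$pseudo <- ifelse(ft$pseudo, "true", NA_character_)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(path)
}

#' Codon usage table of a set of coding sequences
#'
#' Tallies every codon over the coding strands of the supplied CDS records
#' (the CUSP-style table: counts, within-synonymous-family fractions, and
#' frequency per 1000 codons) under the bacterial genetic code. Codons
#' containing `N` are excluded from the tally.
#'
#' @param cds_records output of [extract_cds_records()], or a character
#'   vector of coding sequences.
#' @return `data.frame` with 64 rows: `codon`, `aa`, `count`, `fraction`,
#'   `per_thousand`.
#' @export
compute_codon_usage <- function(cds_records) {
  seqs <- if (is.character(cds_records)) cds_records else cds_records$coding_sequence
  if (length(seqs) == 0L) stop("no coding sequences: cannot compute codon usage")
  if (any(nchar(seqs) %% 3L != 0L)) stop("coding sequence length not divisible by 3")
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  counts <- setNames(integer(64), codons)
  for (s in seqs) {
    cs <- substring(s, seq(1L, nchar(s) - 2L, by = 3L), seq(3L, nchar(s), by = 3L))
    cs <- cs[!grepl("N", cs, fixed = TRUE)]
    tb <- table(cs)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  total <- sum(counts)
  if (total == 0L) stop("no countable codons")
  aa <- unname(gc[codons])
  aa[codons %in% STOP_CODONS] <- "*"
  fam_tot <- tapply(counts, aa, sum)[aa]
  fraction <- ifelse(fam_tot > 0, counts / fam_tot, 0)
  data.frame(codon = codons, aa = aa, count = unname(counts),
             fraction = unname(fraction),
             per_thousand = unname(1000 * counts / total),
             stringsAsFactors = FALSE)
}

#' Rank of a codon by usage
#'
#' @param usage a table from [compute_codon_usage()].
#' @param codon codon string (DNA alphabet).
#' @return integer rank (1 = most frequent, ties share the minimum rank).
#' @export
codon_usage_rank <- function(usage, codon) {
  codon <- toupper(gsub("U", "T", codon))
  r <- rank(-usage$per_thousand, ties.method = "min")
  i <- match(codon, usage$codon)
  if (is.na(i)) stop("unknown codon: ", codon)
  as.integer(r[i])
}

hit_columns <- c("cds_id", "protospacer_seq", "pam_seq", "genome_start",
                 "genome_end", "protospacer_strand", "orientation",
                 "window_c_offsets", "n_stop_edits", "stop_offsets",
                 "stop_codon_index", "wt_codon", "mutant_codon",
                 "cds_fraction", "quality")

#' Write protospacer hits to disk
#'
#' TSV carries one row per hit with the documented columns; BED6 uses
#' 0-based half-open protospacer intervals with `name` = CDS id and the
#' protospacer strand; JSON is a lossless dump (including the full stop-edit
#' sets) that [read_hits()] restores exactly.
#'
#' @param hits a hit table from [design_knockouts()].
#' @param path output file.
#' @param format `"tsv"`, `"bed"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, format = c("tsv", "bed", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    flat <- hits[intersect(hit_columns, names(hits))]
    utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "bed") {
    if (nrow(hits) == 0L) {
      file.create(path)
      return(invisible(path))
    }
    bed <- data.frame(chrom = attr(hits, "genome_id") %||% ".",
                      start = hits$genome_start - 1L,
                      end = hits$genome_end,
                      name = hits$cds_id,
                      score = 0L,
                      strand = hits$protospacer_strand)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    payload <- list(genome_id = attr(hits, "genome_id") %||% NA_character_,
                    hits = hits,
                    stop_edits = attr(hits, "stop_edits"))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read protospacer hits from a JSON dump
#'
#' @param path JSON written by [write_hits()].
#' @return the hit table, with `genome_id` and `stop_edits` attributes.
#' @export
read_hits <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  hits <- as.data.frame(payload$hits, stringsAsFactors = FALSE)
  for (col in c("genome_start", "genome_end", "n_stop_edits", "stop_codon_index")) {
    if (col %in% names(hits)) hits[[col]] <- as.integer(hits[[col]])
  }
  attr(hits, "genome_id") <- payload$genome_id
  se <- payload$stop_edits
  if (!is.null(se)) {
    attr(hits, "stop_edits") <- lapply(se, function(d) {
      d <- as.data.frame(d, stringsAsFactors = FALSE)
      if ("codon_index" %in% names(d)) d$codon_index <- as.integer(d$codon_index)
      d
    })
  }
  hits
}
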