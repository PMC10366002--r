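#' Construct an annotated genome
#'
#' The central container of the package: a single replicon (chromosome or
#' plasmid) with its CDS annotations. All coordinates are 1-based inclusive
#' on the forward strand; a CDS with `end < start` wraps the origin and is
#' only legal on a circular genome.
#'
#' @param id replicon identifier (e.g. an accession).
#' @param sequence DNA string over `A,C,G,T,N` (case-insensitive; stored
#'   upper-case).
#' @param features `data.frame` with columns `id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`) and optionally `pseudo` (logical). One row per CDS.
#' @param circular is the replicon circular?
#' @return an object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence, features = NULL, circular = FALSE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) stop("sequence contains non-ACGTN characters")
  if (is.null(features)) {
    features <- data.frame(id = character(), start = integer(), end = integer(),
                           strand = character(), pseudo = logical())
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!"pseudo" %in% names(features)) features$pseudo <- rep(FALSE, nrow(features))
  need <- c("id", "start", "end", "strand", "pseudo")
  if (!all(need %in% names(features))) {
    stop("features must have columns ", paste(need, collapse = ", "))
  }
  features <- features[need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  n <- nchar(sequence)
  if (nrow(features)) {
    if (anyDuplicated(features$id)) stop("feature identifiers must be unique")
    if (any(features$start < 1L | features$start > n | features$end < 1L | features$end > n)) {
      stop("feature interval outside [1, genome length]")
    }
    if (!circular && any(features$end < features$start)) {
      stop("origin-wrapping CDS on a linear genome")
    }
    if (!all(features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    o <- order(features$start, features$strand)  # '+' < '-' in C locale
    features <- features[o, , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features),
            class = "annotated_genome")
}

#' @exportS3Method base::print
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %s, %d CDS (%d pseudo)\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features), sum(x$features$pseudo)))
  invisible(x)
}

genome_length <- function(genome) nchar(genome$sequence)

# Genomic length of a (possibly origin-wrapping) feature interval.
feature_span <- function(start, end, glen) {
  ifelse(end >= start, end - start + 1L, glen - start + 1L + end)
}

#' Extract coding-sequence records from a genome
#'
#' Returns the non-pseudo CDS features with their coding-strand sequence:
#' minus-strand records carry the reverse complement of the genomic
#' interval, read 5'->3' on the coding strand. Records are ordered by
#' genomic start, `+` before `-` on ties.
#'
#' @param genome an [annotated_genome()].
#' @param include_pseudo also return records flagged pseudo (excluded from
#'   design scans by default).
#' @return `data.frame` with columns `id`, `start`, `end`, `strand`,
#'   `pseudo`, `length`, `coding_sequence`.
#' @export
extract_cds_records <- function(genome, include_pseudo = FALSE) {
  ft <- genome$features
  if (!include_pseudo) ft <- ft[!ft$pseudo, , drop = FALSE]
  glen <- genome_length(genome)
  if (nrow(ft) == 0L) {
    return(cbind(ft, data.frame(length = integer(), coding_sequence = character())))
  }
  span <- feature_span(ft$start, ft$end, glen)
  cs <- character(nrow(ft))
  for (i in seq_len(nrow(ft))) {
    e <- if (ft$end[i] >= ft$start[i]) ft$end[i] else ft$end[i] + glen
    s <- genome_substr(genome$sequence, ft$start[i], e, genome$circular)
    cs[i] <- if (ft$strand[i] == "+") s else revcomp(s)
  }
  ft$length <- as.integer(span)
  ft$coding_sequence <- cs
  rownames(ft) <- NULL
  ft
}

# Coding-strand position (1-based within the CDS) of genomic position g.
# For wrapping CDSs g must be given unwrapped (possibly > genome length).
cds_coding_pos <- function(g, start, end, strand, glen) {
  e <- ifelse(end >= start, end, end + glen)
  if (strand == "+") g - start + 1L else e - g + 1L
}

#' List genes wholly contained in a genomic region
#'
#' Used to characterise large deletion events: which annotated CDSs fall
#' entirely inside a region of the genome (e.g. a region whose sequencing
#' coverage dropped to zero).
#'
#' @param genome an [annotated_genome()].
#' @param start 1-based first position of the region.
#' @param size region length in nt.
#' @param include_pseudo count pseudo-flagged CDSs too (default `TRUE`:
#'   a deletion removes them regardless of coding status).
#' @return `data.frame` of the contained CDS features.
#' @export
genes_in_region <- function(genome, start, size, include_pseudo = TRUE) {
  ft <- genome$features
  if (!include_pseudo) ft <- ft[!ft$pseudo, , drop = FALSE]
  stop_at <- start + size - 1L
  keep <- ft$end >= ft$start & ft$start >= start & ft$end <= stop_at
  out <- ft[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
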