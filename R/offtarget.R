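#' Off-target search query
#'
#' A spacer with its search limits, following Cas-Offinder bulge semantics:
#' a DNA bulge is an extra unpaired base on the genomic target (the query
#' gains a wildcard insertion), an RNA bulge is an extra base on the spacer
#' RNA (the query loses a base).
#'
#' @param label query name, e.g. `"CLAU1794G"`.
#' @param spacer spacer sequence (DNA alphabet, length >= 10).
#' @param pam_pattern IUPAC PAM required immediately 3' of the target on
#'   the target strand.
#' @param max_mismatches,max_dna_bulge,max_rna_bulge search limits (>= 0).
#' @return an `offtarget_query` object.
#' @export
offtarget_query <- function(label, spacer, pam_pattern = "NGG",
                            max_mismatches = 9L, max_dna_bulge = 2L,
                            max_rna_bulge = 2L) {
  spacer <- toupper(spacer)
  if (grepl("[^ACGT]", spacer)) stop("spacer contains non-DNA characters")
  if (nchar(spacer) < 10L) stop("spacer must be at least 10 nt")
  if (max_mismatches < 0L || max_dna_bulge < 0L || max_rna_bulge < 0L) {
    stop("search limits must be non-negative")
  }
  structure(list(label = label, spacer = spacer,
                 pam_pattern = toupper(pam_pattern),
                 max_mismatches = as.integer(max_mismatches),
                 max_dna_bulge = as.integer(max_dna_bulge),
                 max_rna_bulge = as.integer(max_rna_bulge)),
            class = "offtarget_query")
}

#' Expand a query into its gapped pattern set
#'
#' Returns the ungapped spacer, every pattern obtained by deleting a
#' contiguous interior run of up to `max_rna_bulge` bases (RNA bulge), and
#' every pattern obtained by inserting a contiguous run of up to
#' `max_dna_bulge` `N` wildcards at an interior junction (DNA bulge).
#' Terminal bulges are excluded (equivalent to a shorter or shifted
#' ungapped match). The set is deduplicated on the pattern string within
#' each bulge size, in deterministic order.
#'
#' @param query an [offtarget_query()].
#' @return `data.frame` with columns `pattern`, `bulge_type`, `bulge_size`,
#'   `bulge_pos` (1-based position in the spacer of the first deleted base,
#'   or the junction after which Ns were inserted; 0 for the ungapped
#'   spacer), `gap_query_pos` (positions of `-` in the aligned query, comma
#'   string) and `gap_target_pos` (positions of `-` in the aligned target).
#' @export
generate_query_variants <- function(query) {
  sp <- query$spacer
  L <- nchar(sp)
  ch <- seq_chars(sp)
  rows <- list(data.frame(pattern = sp, bulge_type = "none", bulge_size = 0L,
                          bulge_pos = 0L, stringsAsFactors = FALSE))
  if (query$max_rna_bulge > 0L) {
    for (k in seq_len(query$max_rna_bulge)) {
      for (i in 2:(L - k)) {                  # run i..i+k-1 strictly interior
        rows[[length(rows) + 1L]] <- data.frame(
          pattern = paste(ch[-(i:(i + k - 1L))], collapse = ""),
          bulge_type = "RNA", bulge_size = k, bulge_pos = i,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (query$max_dna_bulge > 0L) {
    for (k in seq_len(query$max_dna_bulge)) {
      for (i in 1:(L - 1L)) {                 # insert after position i
        rows[[length(rows) + 1L]] <- data.frame(
          pattern = paste(c(ch[1:i], rep("N", k), ch[(i + 1L):L]), collapse = ""),
          bulge_type = "DNA", bulge_size = k, bulge_pos = i,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$pattern, out$bulge_size)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)

encode_dna <- function(x) unname(DNA_CODE[seq_chars(x)])

# Positions (1-based) where `pattern` matches `codes` with <= max_mm
# mismatches; pattern N is a wildcard, subject N always mismatches.
# Returns data.frame(pos, mm).
scan_pattern_mismatches <- function(codes, pattern, max_mm) {
  l <- nchar(pattern)
  np <- length(codes) - l + 1L
  if (np < 1L) return(data.frame(pos = integer(), mm = integer()))
  pc <- encode_dna(pattern)
  mm <- integer(np)
  idx <- seq_len(np)
  for (j in seq_len(l)) {
    if (pc[j] == 0L) next
    mm <- mm + (codes[idx + j - 1L] != pc[j])
  }
  keep <- mm <= max_mm
  data.frame(pos = idx[keep], mm = mm[keep])
}

#' Search a genome for off-target sites of a spacer
#'
#' Scans both strands for gapped-pattern matches within the query's
#' mismatch and bulge limits, requiring the query's PAM pattern immediately
#' 3' of the aligned target on the target strand. In `"primary"` mode each
#' (position, strand) is reported once with its best alignment (fewest
#' mismatches, then smallest bulge, then bulge type none < RNA < DNA); in
#' `"raw"` mode every (position, strand, pattern variant) combination is
#' reported, which is the counting convention of bulge-aware off-target
#' scanners and is needed for count parity with them.
#'
#' @param genome an [annotated_genome()].
#' @param query an [offtarget_query()].
#' @param mode `"primary"` or `"raw"`.
#' @param region optional `c(start, end)` restricting the scan to a
#'   forward-strand interval of the genome.
#' @return `data.frame` with columns `query_label`, `genome_position`
#'   (1-based leftmost base of the aligned target on the forward strand),
#'   `genome_end`, `strand`, `mismatches`, `bulge_type`, `bulge_size`,
#'   `aligned_target`, `aligned_query`, `pam_seq`; sorted by position.
#' @export
search_offtargets <- function(genome, query, mode = c("primary", "raw"),
                              region = NULL) {
  mode <- match.arg(mode)
  offset <- 0L
  s <- genome$sequence
  circular <- genome$circular
  if (!is.null(region)) {
    s <- substr(s, region[1], region[2])
    offset <- region[1] - 1L
    circular <- FALSE
  }
  n <- nchar(s)
  variants <- generate_query_variants(query)
  Lp <- nchar(query$pam_pattern)
  maxlen <- max(nchar(variants$pattern)) + Lp
  fwd <- if (circular) paste0(s, substr(s, 1L, maxlen - 1L)) else s
  rev <- revcomp(fwd)
  fwd_codes <- encode_dna(fwd)
  rev_codes <- encode_dna(rev)
  fwd_chars <- seq_chars(fwd)
  rev_chars <- seq_chars(rev)
  pam_codes <- seq_chars(query$pam_pattern)
  nf <- length(fwd_codes)

  sp_chars <- seq_chars(query$spacer)
  rows <- list()
  for (v in seq_len(nrow(variants))) {
    pat <- variants$pattern[v]
    l <- nchar(pat)
    for (str in c("+", "-")) {
      codes <- if (str == "+") fwd_codes else rev_codes
      chars <- if (str == "+") fwd_chars else rev_chars
      m <- scan_pattern_mismatches(codes, pat, query$max_mismatches)
      if (nrow(m) == 0L) next
      # PAM immediately 3' on the scanned strand
      ok_pam <- m$pos + l + Lp - 1L <= nf
      m <- m[ok_pam, , drop = FALSE]
      if (nrow(m) == 0L) next
      pam_ok <- match_iupac_at(chars, m$pos + l, pam_codes)
      m <- m[pam_ok, , drop = FALSE]
      if (nrow(m) == 0L) next
      # map to forward coordinates; drop duplicated circular images
      if (str == "+") {
        gstart <- m$pos
      } else {
        gstart <- nf - (m$pos + l - 1L) + 1L
      }
      keep <- gstart >= 1L & gstart <= n
      m <- m[keep, , drop = FALSE]; gstart <- gstart[keep]
      if (nrow(m) == 0L) next
      target <- vapply(m$pos, function(p)
        paste(chars[p:(p + l - 1L)], collapse = ""), character(1))
      pam_seq <- vapply(m$pos, function(p)
        paste(chars[(p + l):(p + l + Lp - 1L)], collapse = ""), character(1))
      al <- aligned_strings(sp_chars, target, variants[v, ])
      rows[[length(rows) + 1L]] <- data.frame(
        query_label = query$label,
        genome_position = gstart + offset,
        genome_end = gstart + l - 1L + offset,
        strand = str, mismatches = m$mm,
        bulge_type = variants$bulge_type[v],
        bulge_size = variants$bulge_size[v],
        aligned_target = al$target, aligned_query = al$query,
        pam_seq = pam_seq, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query_label = character(), genome_position = integer(),
                      genome_end = integer(), strand = character(),
                      mismatches = integer(), bulge_type = character(),
                      bulge_size = integer(), aligned_target = character(),
                      aligned_query = character(), pam_seq = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  if (mode == "primary") {
    type_rank <- c(none = 0L, RNA = 1L, DNA = 2L)
    o <- order(out$genome_position, out$strand, out$mismatches,
               out$bulge_size, type_rank[out$bulge_type])
    out <- out[o, , drop = FALSE]
    out <- out[!duplicated(paste(out$genome_position, out$strand)), , drop = FALSE]
  }
  out <- out[order(out$genome_position, out$strand, out$mismatches), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gapped alignment strings for a pattern variant matched to `target`
# (character vector of matched genomic substrings, pattern length).
aligned_strings <- function(sp_chars, target, variant) {
  if (variant$bulge_type == "none") {
    return(list(query = paste(sp_chars, collapse = ""), target = target))
  }
  k <- variant$bulge_size; i <- variant$bulge_pos
  if (variant$bulge_type == "RNA") {
    # spacer keeps all bases; target gains '-' at the deleted spacer run
    q <- paste(sp_chars, collapse = "")
    t <- vapply(target, function(tt) {
      tc <- seq_chars(tt)
      paste(append(tc, rep("-", k), after = i - 1L), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    list(query = q, target = t)
  } else {
    # DNA bulge: query gains '-' where the target has extra bases
    q <- paste(append(sp_chars, rep("-", k), after = i), collapse = "")
    list(query = q, target = target)
  }
}

#' Read variant records from a VCF file
#'
#' @param path VCF path (plain text or bgzipped).
#' @return `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `annotation` (the INFO field).
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS), ref = fx$REF,
             alt = fx$ALT,
             annotation = if ("INFO" %in% names(fx)) fx$INFO else NA_character_,
             stringsAsFactors = FALSE)
}

#' Associate variants with off-target sites by proximity
#'
#' A variant is associated with every site whose occupied interval lies
#' within `max_distance` nt of it (inclusive); the distance to a variant
#' inside the interval is 0.
#'
#' @param sites output of [search_offtargets()] (possibly several queries
#'   row-bound together).
#' @param variants output of [read_variants()] or a compatible data frame.
#' @param max_distance association threshold in nt (default 50).
#' @return `data.frame`: one row per (variant, site) association with
#'   `chrom`, `pos`, `ref`, `alt`, `query_label`, `site_position`,
#'   `strand`, `mismatches`, `bulge_size`, `distance`.
#' @export
associate_variants <- function(sites, variants, max_distance = 50L) {
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    vp <- variants$pos[i]
    d <- pmax(sites$genome_position - vp, vp - sites$genome_end, 0L)
    hit <- which(d <= max_distance)
    for (j in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = variants$chrom[i], pos = vp, ref = variants$ref[i],
        alt = variants$alt[i], query_label = sites$query_label[j],
        site_position = sites$genome_position[j], strand = sites$strand[j],
        mismatches = sites$mismatches[j], bulge_size = sites$bulge_size[j],
        distance = d[j], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), query_label = character(),
                      site_position = integer(), strand = character(),
                      mismatches = integer(), bulge_size = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Extract the WT context around a variant
#'
#' The 41-nt wild-type sequence centred on the variant position (20 nt
#' upstream and downstream).
#'
#' @param genome an [annotated_genome()].
#' @param pos 1-based variant position.
#' @param flank bases on each side (default 20).
#' @return character scalar.
#' @export
variant_context <- function(genome, pos, flank = 20L) {
  genome_substr(genome$sequence, pos - flank, pos + flank, genome$circular)
}

#' Local alignment of a spacer against a variant context
#'
#' Smith-Waterman local alignment (match +1, mismatch -1, gap -2 by
#' default) of the spacer, in both orientations, against a short WT context
#' sequence; the fallback matcher for off-target candidates that gapped
#' pattern search misses. The alignment is flagged `reported` when its
#' match count reaches `min_matches`.
#'
#' @param spacer spacer sequence.
#' @param context context sequence (at least as long as the spacer).
#' @param match,mismatch,gap scoring scheme (gap is the per-base penalty).
#' @param min_matches report threshold on the aligned match count.
#' @return one-row `data.frame`: `orientation`, `score`, `matches`,
#'   `mismatches`, `gaps`, `context_start`, `context_end`, `reported`.
#' @export
local_align_fallback <- function(spacer, context, match = 1, mismatch = -1,
                                 gap = -2, min_matches = 11L) {
  spacer <- toupper(spacer); context <- toupper(context)
  if (nchar(context) < nchar(spacer)) {
    stop("context shorter than spacer")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  best <- NULL
  for (ori in c("+", "-")) {
    q <- if (ori == "+") spacer else revcomp(spacer)
    aln <- Biostrings::pairwiseAlignment(
      pattern = q, subject = context, type = "local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap)
    pa <- as.character(Biostrings::alignedPattern(aln))
    sa <- as.character(Biostrings::alignedSubject(aln))
    gaps <- sum(seq_chars(pa) == "-") + sum(seq_chars(sa) == "-")
    rec <- data.frame(orientation = ori,
                      score = Biostrings::score(aln),
                      matches = Biostrings::nmatch(aln),
                      mismatches = Biostrings::nmismatch(aln),
                      gaps = gaps,
                      context_start = Biostrings::start(Biostrings::subject(aln)),
                      context_end = Biostrings::end(Biostrings::subject(aln)),
                      stringsAsFactors = FALSE)
    if (is.null(best) || rec$score > best$score) best <- rec
  }
  best$reported <- best$matches >= min_matches
  best
}
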