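#' PAM specification
#'
#' Describes a Cas9 variant by its protospacer-adjacent motif. The pattern
#' is an IUPAC string matched immediately 3' of the protospacer on the
#' protospacer strand; `NG` is treated as a literal 2-nt PAM.
#'
#' @param pattern IUPAC DNA pattern, e.g. `"NGG"`, `"NG"`, `"NAA"`.
#' @param name editor name for reports (defaults to the pattern).
#' @param spacer_length protospacer length in nt (default 20).
#' @return a `pam_spec` object.
#' @export
pam_spec <- function(pattern, name = pattern, spacer_length = 20L) {
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0L || grepl("[^ACGTRYSWKMBDHVN]", pattern)) {
    stop("invalid IUPAC PAM pattern: ", pattern)
  }
  structure(list(name = name, pattern = pattern,
                 spacer_length = as.integer(spacer_length)),
            class = "pam_spec")
}

#' Editing window
#'
#' PAM-relative positions (negative, `-1` = PAM-proximal protospacer base)
#' where the deaminase converts C to T on the protospacer strand. The
#' default `-19..-16` is the window used for genome-wide targeting-space
#' modelling; `-20..-16` is selectable.
#'
#' @param from_pos,to_pos inclusive window bounds (negative integers,
#'   `from_pos <= to_pos`).
#' @return an `editing_window` object.
#' @export
editing_window <- function(from_pos = -19L, to_pos = -16L) {
  from_pos <- as.integer(from_pos); to_pos <- as.integer(to_pos)
  if (from_pos > to_pos || to_pos > -1L) stop("need from_pos <= to_pos <= -1")
  structure(list(from_pos = from_pos, to_pos = to_pos), class = "editing_window")
}

window_offsets <- function(window) seq.int(window$from_pos, window$to_pos)

#' Scan a genome for PAM occurrences on both strands
#'
#' Every returned site matches the IUPAC pattern on its own strand and has
#' at least `spacer_length` bases 5' of it (wrapping across the origin when
#' the genome is circular). `N` bases in the genome never match a PAM.
#'
#' @param genome an [annotated_genome()].
#' @param pam a [pam_spec()].
#' @return `data.frame` with columns `pam_start`, `pam_end` (1-based
#'   forward-strand interval of the PAM; for circular genomes the start is
#'   in `[1, length]` and the end may run past the origin unwrapped),
#'   `strand`, `proto_start`, `proto_end` (protospacer interval, unwrapped:
#'   may be `< 1` or `> length` on a circular genome).
#' @export
scan_pam_sites <- function(genome, pam) {
  s <- genome$sequence
  n <- nchar(s)
  Lp <- nchar(pam$pattern)
  S <- pam$spacer_length
  scan_seq <- if (genome$circular) paste0(s, substr(s, 1L, Lp - 1L)) else s
  subj <- Biostrings::DNAString(scan_seq)

  find <- function(pattern) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subj,
                                  fixed = "subject")
    Biostrings::start(m)
  }

  plus <- find(pam$pattern)
  minus <- find(revcomp(pam$pattern))
  plus <- plus[plus <= n]
  minus <- minus[minus <= n]

  out <- rbind(
    if (length(plus)) data.frame(pam_start = plus, strand = "+",
                                 proto_start = plus - S, proto_end = plus - 1L),
    if (length(minus)) data.frame(pam_start = minus, strand = "-",
                                  proto_start = minus + Lp,
                                  proto_end = minus + Lp + S - 1L)
  )
  if (is.null(out)) {
    out <- data.frame(pam_start = integer(), strand = character(),
                      proto_start = integer(), proto_end = integer())
  }
  out$pam_end <- out$pam_start + Lp - 1L
  if (!genome$circular) {
    keep <- out$proto_start >= 1L & out$proto_end <= n & out$pam_end <= n
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$pam_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out[c("pam_start", "pam_end", "strand", "proto_start", "proto_end")]
}

# Genomic (forward, unwrapped) position of PAM-relative offset o for a site.
offset_to_genomic <- function(pam_start, pam_end, strand, o) {
  if (strand == "+") pam_start + o else pam_end - o
}

#' Enumerate STOP-producing edit subsets of one protospacer
#'
#' Considers every non-empty subset of editing-window positions that carry
#' a C on the protospacer strand, applies C->T on the protospacer strand
#' (equivalently G->A on the coding strand for antisense protospacers), and
#' reports each subset that turns an in-frame coding-strand codon into
#' TAA, TAG or TGA. Only codons lying wholly within the protospacer
#' footprint are evaluated here; [design_knockouts()] evaluates the full
#' CDS context instead.
#'
#' @param protospacer_seq protospacer (5'->3' on the protospacer strand).
#' @param orientation `"sense"` if the protospacer strand is the coding
#'   strand, `"antisense"` otherwise.
#' @param frame_offset 0..2: phase of the coding fragment's first base in
#'   the reading frame (0 = starts a codon). The coding fragment is the
#'   protospacer itself (sense) or its reverse complement (antisense).
#' @param window an [editing_window()].
#' @return `data.frame` with one row per (subset, codon) stop outcome:
#'   `edited_offsets` (comma-joined PAM-relative positions), `codon_index`
#'   (0-based within the coding fragment's frame), `wt_codon`,
#'   `mutant_codon`, `stop_triplet`.
#' @export
stop_edits_for_protospacer <- function(protospacer_seq,
                                       orientation = c("sense", "antisense"),
                                       frame_offset = 0L,
                                       window = editing_window()) {
  orientation <- match.arg(orientation)
  frame_offset <- as.integer(frame_offset)
  if (is.na(frame_offset) || frame_offset < 0L || frame_offset > 2L) {
    stop("frame_offset must be 0, 1 or 2")
  }
  p <- toupper(protospacer_seq)
  S <- nchar(p)
  offs <- window_offsets(window)
  idx <- S + 1L + offs                      # protospacer index of each offset
  idx_ok <- idx >= 1L & idx <= S
  offs <- offs[idx_ok]; idx <- idx[idx_ok]
  pc <- seq_chars(p)
  c_offs <- offs[pc[idx] == "C"]
  empty <- data.frame(edited_offsets = character(), codon_index = integer(),
                      wt_codon = character(), mutant_codon = character(),
                      stop_triplet = character(), stringsAsFactors = FALSE)
  if (length(c_offs) == 0L) return(empty)

  frag <- if (orientation == "sense") pc else seq_chars(revcomp(p))
  # fragment index of protospacer index i
  frag_index <- function(i) if (orientation == "sense") i else S + 1L - i
  edited_base <- if (orientation == "sense") "T" else "A"   # C->T / G->A

  rows <- list()
  for (subset in nonempty_subsets(sort(c_offs))) {
    fidx <- vapply(subset, function(o) frag_index(S + 1L + o), integer(1))
    g0 <- fidx - 1L + frame_offset          # 0-based coding coordinate
    for (k in unique(g0 %/% 3L)) {
      codon_g <- 3L * k + (0:2)             # coding coords of codon k
      fpos <- codon_g - frame_offset + 1L   # fragment positions
      if (any(fpos < 1L | fpos > S)) next   # codon not wholly in fragment
      wt <- frag[fpos]
      mut <- wt
      mut[fpos %in% fidx] <- edited_base
      wt_c <- paste(wt, collapse = ""); mut_c <- paste(mut, collapse = "")
      if (!(wt_c %in% STOP_CODONS) && mut_c %in% STOP_CODONS) {
        rows[[length(rows) + 1L]] <- data.frame(
          edited_offsets = paste(sort(subset), collapse = ","),
          codon_index = k, wt_codon = wt_c, mutant_codon = mut_c,
          stop_triplet = mut_c, n_edits = length(subset),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$codon_index, out$n_edits, out$edited_offsets), , drop = FALSE]
  rownames(out) <- NULL
  out[setdiff(names(out), "n_edits")]
}

#' Classify protospacer quality from its window cytosines
#'
#' Editing outcome quality as recommended for guide selection: a single
#' window C at -18 or -19 is `clean`; two or more window Cs is `multi_C`
#' (risk of mixed colonies, each lineage editing a different C); a single C
#' at -17 or -16 is `window_edge` (rarely edited successfully).
#'
#' @param window_c_offsets integer vector (or comma-joined string) of
#'   PAM-relative window positions carrying a C.
#' @return `"clean"`, `"multi_C"` or `"window_edge"`.
#' @export
classify_quality <- function(window_c_offsets) {
  if (is.character(window_c_offsets)) {
    window_c_offsets <- as.integer(strsplit(window_c_offsets, ",")[[1]])
  }
  if (length(window_c_offsets) == 0L) stop("no window cytosines to classify")
  if (length(window_c_offsets) >= 2L) return("multi_C")
  if (window_c_offsets %in% c(-18L, -19L)) "clean" else "window_edge"
}

#' @rdname classify_quality
#' @param hit one row (or the whole table) of a [design_knockouts()] result.
#' @export
classify_hit <- function(hit) {
  vapply(hit$window_c_offsets, classify_quality, character(1), USE.NAMES = FALSE)
}

#' Design STOP-introducing base-editor protospacers genome-wide
#'
#' Scans both strands of the genome for PAM sites, and reports one hit per
#' (protospacer site, CDS) pair for which at least one non-empty subset of
#' editing-window cytosines, converted C->T on the protospacer strand,
#' creates an in-frame premature STOP codon lying wholly within the CDS and
#' within the first `first_fraction` of the CDS. The PAM and parts of the
#' protospacer may lie outside the CDS.
#'
#' @param genome an [annotated_genome()] with at least one non-pseudo CDS.
#' @param pam a [pam_spec()].
#' @param window an [editing_window()].
#' @param first_fraction keep only stops whose codon starts within this
#'   leading fraction of the CDS (default 0.75).
#' @param anchor `"stop"` anchors the fraction rule on the first base of
#'   the would-be stop codon; `"protospacer"` anchors it on the coding
#'   position of the protospacer's 5'-most base (clamped into the CDS).
#' @param subset_mode `"any"` enumerates all non-empty window-C subsets;
#'   `"single"` restricts to single-C edits.
#' @return `data.frame` of hits sorted by `genome_start` (`+` before `-`),
#'   with attribute `stop_edits`: a list (one element per hit) of the
#'   qualifying edit subsets as returned by [stop_edits_for_protospacer()]
#'   plus the codon's coding position. Attribute `genome_id` records the
#'   source replicon.
#' @export
design_knockouts <- function(genome, pam, window = editing_window(),
                             first_fraction = 0.75,
                             anchor = c("stop", "protospacer"),
                             subset_mode = c("any", "single")) {
  anchor <- match.arg(anchor)
  subset_mode <- match.arg(subset_mode)
  cds <- extract_cds_records(genome)
  empty <- empty_hits(genome$id)
  if (nrow(cds) == 0L) {
    warning("genome has no non-pseudo CDS; returning empty hit set")
    return(empty)
  }
  sites <- scan_pam_sites(genome, pam)
  if (nrow(sites) == 0L) return(empty)
  n <- genome_length(genome)
  S <- pam$spacer_length
  ext <- if (genome$circular) paste0(genome$sequence, genome$sequence) else genome$sequence

  # protospacer sequences (vectorised); circular plus-strand sites with
  # proto_start < 1 are shifted one genome length into the doubled string
  shift <- ifelse(sites$proto_start < 1L, n, 0L)
  fwd <- substring(ext, sites$proto_start + shift, sites$proto_end + shift)
  proto <- ifelse(sites$strand == "+", fwd, revcomp(fwd))
  pam_fwd <- substring(ext, sites$pam_start + ifelse(sites$pam_start < 1L, n, 0L),
                       sites$pam_end + ifelse(sites$pam_start < 1L, n, 0L))
  pam_seq <- ifelse(sites$strand == "+", pam_fwd, revcomp(pam_fwd))

  offs <- window_offsets(window)
  idx <- S + 1L + offs
  keep_o <- idx >= 1L & idx <= S
  offs <- offs[keep_o]; idx <- idx[keep_o]
  # window C mask per site
  win_c <- lapply(seq_len(nrow(sites)), function(i) {
    offs[substring(proto[i], idx, idx) == "C"]
  })
  has_c <- lengths(win_c) > 0L
  sites <- sites[has_c, , drop = FALSE]
  proto <- proto[has_c]; pam_seq <- pam_seq[has_c]; win_c <- win_c[has_c]
  if (nrow(sites) == 0L) return(empty)

  # candidate (site, CDS) pairs: window interval (padded 2 nt for codon
  # overhang) against CDS intervals, on unwrapped coordinates
  win_lo <- integer(nrow(sites)); win_hi <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    g <- vapply(win_c[[i]], function(o)
      offset_to_genomic(sites$pam_start[i], sites$pam_end[i], sites$strand[i], o),
      numeric(1))
    win_lo[i] <- min(g); win_hi[i] <- max(g)
  }
  cds_start <- cds$start
  cds_end <- ifelse(cds$end >= cds$start, cds$end, cds$end + n)
  shifts <- if (genome$circular) c(-n, 0L, n) else 0L
  pair_site <- integer(0); pair_cds <- integer(0); pair_shift <- integer(0)
  for (sh in shifts) {
    q <- IRanges::IRanges(start = win_lo - 2L + sh, end = win_hi + 2L + sh)
    s_ir <- IRanges::IRanges(start = cds_start, end = cds_end)
    ov <- IRanges::findOverlaps(q, s_ir)
    pair_site <- c(pair_site, S4Vectors::queryHits(ov))
    pair_cds <- c(pair_cds, S4Vectors::subjectHits(ov))
    pair_shift <- c(pair_shift, rep(sh, length(ov)))
  }
  if (length(pair_site) == 0L) return(empty)
  dup <- duplicated(paste(pair_site, pair_cds))
  pair_site <- pair_site[!dup]; pair_cds <- pair_cds[!dup]
  pair_shift <- pair_shift[!dup]

  hits <- list(); edits_per_hit <- list()
  for (p in seq_along(pair_site)) {
    i <- pair_site[p]; j <- pair_cds[p]; sh <- pair_shift[p]
    res <- site_cds_stop_edits(
      pam_start = sites$pam_start[i] + sh, pam_end = sites$pam_end[i] + sh,
      strand = sites$strand[i], win_c = win_c[[i]],
      cds_start = cds_start[j], cds_end = cds_end[j],
      cds_strand = cds$strand[j], coding = cds$coding_sequence[j],
      first_fraction = first_fraction, anchor = anchor,
      subset_mode = subset_mode, spacer_length = S)
    if (is.null(res)) next
    frac <- res$cds_fraction
    hits[[length(hits) + 1L]] <- data.frame(
      cds_id = cds$id[j],
      protospacer_seq = tolower(proto[i]),
      pam_seq = tolower(pam_seq[i]),
      genome_start = wrap_pos(sites$proto_start[i], n),
      genome_end = wrap_pos(sites$proto_end[i], n),
      protospacer_strand = sites$strand[i],
      orientation = if (sites$strand[i] == cds$strand[j]) "sense" else "antisense",
      window_c_offsets = paste(sort(win_c[[i]]), collapse = ","),
      n_stop_edits = nrow(res$edits),
      stop_offsets = res$edits$edited_offsets[1],
      stop_codon_index = res$edits$codon_index[1],
      wt_codon = res$edits$wt_codon[1],
      mutant_codon = res$edits$mutant_codon[1],
      cds_fraction = frac,
      quality = classify_quality(win_c[[i]]),
      stringsAsFactors = FALSE)
    edits_per_hit[[length(edits_per_hit) + 1L]] <- res$edits
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  o <- order(out$genome_start, out$protospacer_strand, out$cds_id)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stop_edits") <- edits_per_hit[o]
  attr(out, "genome_id") <- genome$id
  out
}

empty_hits <- function(genome_id) {
  out <- data.frame(cds_id = character(), protospacer_seq = character(),
                    pam_seq = character(), genome_start = integer(),
                    genome_end = integer(), protospacer_strand = character(),
                    orientation = character(), window_c_offsets = character(),
                    n_stop_edits = integer(), stop_offsets = character(),
                    stop_codon_index = integer(), wt_codon = character(),
                    mutant_codon = character(), cds_fraction = numeric(),
                    quality = character(), stringsAsFactors = FALSE)
  attr(out, "stop_edits") <- list()
  attr(out, "genome_id") <- genome_id
  out
}

# Stop-edit enumeration for one (site, CDS) pair in full CDS context.
# Coordinates are unwrapped (cds_end >= cds_start, site shifted to match).
# Returns NULL or list(edits = data.frame, cds_fraction = numeric).
site_cds_stop_edits <- function(pam_start, pam_end, strand, win_c,
                                cds_start, cds_end, cds_strand, coding,
                                first_fraction, anchor, subset_mode,
                                spacer_length = 20L) {
  len <- nchar(coding)
  g <- vapply(win_c, function(o) offset_to_genomic(pam_start, pam_end, strand, o),
              numeric(1))
  cpos <- if (cds_strand == "+") g - cds_start + 1 else cds_end - g + 1
  inside <- cpos >= 1 & cpos <= len
  edited_base <- if (strand == cds_strand) "T" else "A"  # C->T vs G->A on coding
  coding_chars <- seq_chars(coding)

  subsets <- nonempty_subsets(sort(win_c))
  if (subset_mode == "single") subsets <- subsets[lengths(subsets) == 1L]
  rows <- list()
  off_to_cpos <- setNames(cpos, as.character(win_c))
  off_inside <- setNames(inside, as.character(win_c))
  for (subset in subsets) {
    cp <- off_to_cpos[as.character(subset)]
    cp <- cp[off_inside[as.character(subset)]]
    if (length(cp) == 0L) next
    for (k in unique((cp - 1) %/% 3)) {
      c1 <- 3 * k + 1
      if (c1 + 2 > len) next
      wt <- coding_chars[c1:(c1 + 2)]
      mut <- wt
      mut[(c1:(c1 + 2)) %in% cp] <- edited_base
      wt_c <- paste(wt, collapse = ""); mut_c <- paste(mut, collapse = "")
      if (!(wt_c %in% STOP_CODONS) && mut_c %in% STOP_CODONS) {
        rows[[length(rows) + 1L]] <- data.frame(
          edited_offsets = paste(sort(subset), collapse = ","),
          codon_index = as.integer(k), wt_codon = wt_c, mutant_codon = mut_c,
          stop_triplet = mut_c, coding_pos = as.integer(c1),
          n_edits = length(subset), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  edits <- do.call(rbind, rows)
  edits <- edits[order(edits$codon_index, edits$n_edits, edits$edited_offsets), ,
                 drop = FALSE]
  if (anchor == "stop") {
    frac <- edits$coding_pos / len
  } else {
    # coding position of the protospacer's 5'-most base (the base at PAM
    # offset -spacer_length), clamped into the CDS
    g5 <- if (strand == "+") pam_start - spacer_length else pam_end + spacer_length
    cp5 <- if (cds_strand == "+") g5 - cds_start + 1 else cds_end - g5 + 1
    cp5 <- min(max(cp5, 1), len)
    frac <- rep(cp5 / len, nrow(edits))
  }
  keep <- frac <= first_fraction
  if (!any(keep)) return(NULL)
  edits <- edits[keep, , drop = FALSE]
  rownames(edits) <- NULL
  list(edits = edits[setdiff(names(edits), "n_edits")],
       cds_fraction = min(frac[keep]))
}
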