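# Independent brute-force oracles. These deliberately share no code with
# the package implementation: character loops, whole-genome re-editing and
# re-translation instead of window arithmetic.

IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

chars <- function(x) strsplit(x, "")[[1]]
rc <- function(x) bestop::revcomp(x)

iupac_ok <- function(subject_chars, pattern) {
  pc <- chars(pattern)
  if (length(subject_chars) != length(pc)) return(FALSE)
  all(vapply(seq_along(pc),
             function(j) subject_chars[j] %in% IUPAC[[pc[j]]], logical(1)))
}

# Character-by-character PAM scanner (linear genomes).
oracle_scan_pam <- function(genome, pattern, spacer_len = 20L) {
  s <- chars(genome$sequence)
  n <- length(s)
  Lp <- nchar(pattern)
  out <- list()
  for (p in seq_len(n - Lp + 1L)) {
    if (iupac_ok(s[p:(p + Lp - 1L)], pattern) && p - spacer_len >= 1L) {
      out[[length(out) + 1L]] <- data.frame(pam_start = p, strand = "+")
    }
  }
  rs <- chars(rc(genome$sequence))
  for (p in seq_len(n - Lp + 1L)) {
    if (iupac_ok(rs[p:(p + Lp - 1L)], pattern) && p - spacer_len >= 1L) {
      # map the rc-coordinate PAM back to forward coordinates
      fstart <- n - (p + Lp - 1L) + 1L
      out[[length(out) + 1L]] <- data.frame(pam_start = fstart, strand = "-")
    }
  }
  if (!length(out)) return(data.frame(pam_start = integer(), strand = character()))
  d <- do.call(rbind, out)
  d[order(d$pam_start, d$strand), , drop = FALSE]
}

# Exhaustive knockout-design oracle: apply every window-C subset edit to a
# copy of the genome, re-extract every CDS, and look for new in-frame
# stops. Returns unique (proto_start, proto_end, strand, cds_id) pairs.
oracle_design <- function(genome, pam_pattern, spacer_len = 20L,
                          window = c(-19L, -16L), first_fraction = 0.75) {
  s <- chars(genome$sequence)
  n <- length(s)
  Lp <- nchar(pam_pattern)
  cds <- bestop::extract_cds_records(genome)
  pairs <- list()
  subsets_of <- function(x) {
    if (length(x) == 1L) return(list(x))
    out <- list()
    for (k in seq_along(x)) {
      out <- c(out, lapply(utils::combn(seq_along(x), k, simplify = FALSE),
                           function(i) x[i]))
    }
    out
  }
  orig_codons <- lapply(seq_len(nrow(cds)), function(j) {
    cc <- cds$coding_sequence[j]
    substring(cc, seq(1, nchar(cc) - 2, 3), seq(3, nchar(cc), 3))
  })
  stops <- c("TAA", "TAG", "TGA")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  # forward positions of each CDS in coding order (+ complement flag)
  cds_idx <- lapply(seq_len(nrow(cds)), function(j) {
    if (cds$strand[j] == "+") cds$start[j]:cds$end[j] else cds$end[j]:cds$start[j]
  })
  consider <- function(proto_start, proto_end, strand, edit_positions) {
    # edit_positions: forward-strand genomic positions to flip
    s2 <- s
    for (g in edit_positions) s2[g] <- if (strand == "+") "T" else "A"
    for (j in seq_len(nrow(cds))) {
      cchars <- s2[cds_idx[[j]]]
      if (cds$strand[j] == "-") cchars <- comp[cchars]
      len <- length(cchars)
      nc <- vapply(seq(1, len - 2, 3),
                   function(a) paste(cchars[a:(a + 2)], collapse = ""),
                   character(1))
      oc <- orig_codons[[j]]
      new_stop <- which(nc %in% stops & !(oc %in% stops))
      for (k in new_stop) {
        if ((3 * (k - 1) + 1) / len <= first_fraction) {
          pairs[[length(pairs) + 1L]] <<- data.frame(
            proto_start = proto_start, proto_end = proto_end, strand = strand,
            cds_id = cds$id[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  for (p in seq_len(n - Lp + 1L)) {
    # plus strand PAM at p
    if (iupac_ok(s[p:(p + Lp - 1L)], pam_pattern) && p - spacer_len >= 1L) {
      proto <- s[(p - spacer_len):(p - 1L)]
      offs <- window[1]:window[2]
      gpos <- p + offs
      cpos <- gpos[proto[spacer_len + 1L + offs] == "C"]
      if (length(cpos)) {
        for (sub in subsets_of(cpos)) consider(p - spacer_len, p - 1L, "+", sub)
      }
    }
    # minus strand: PAM occupies forward [p, p+Lp-1] read as rc
    if (iupac_ok(chars(rc(paste(s[p:(p + Lp - 1L)], collapse = ""))), pam_pattern) &&
        p + Lp - 1L + spacer_len <= n) {
      fw <- s[(p + Lp):(p + Lp + spacer_len - 1L)]
      proto <- chars(rc(paste(fw, collapse = "")))
      offs <- window[1]:window[2]
      gpos <- (p + Lp - 1L) - offs
      cpos <- gpos[proto[spacer_len + 1L + offs] == "C"]
      if (length(cpos)) {
        for (sub in subsets_of(cpos)) {
          consider(p + Lp, p + Lp + spacer_len - 1L, "-", sub)
        }
      }
    }
  }
  if (!length(pairs)) {
    return(data.frame(proto_start = integer(), proto_end = integer(),
                      strand = character(), cds_id = character()))
  }
  d <- unique(do.call(rbind, pairs))
  d <- d[order(d$proto_start, d$strand, d$cds_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

hit_keys <- function(hits) {
  unique(paste(hits$genome_start, hits$genome_end, hits$protospacer_strand,
               hits$cds_id))
}

oracle_keys <- function(od) {
  unique(paste(od$proto_start, od$proto_end, od$strand, od$cds_id))
}

# Exhaustive bulge-aware off-target oracle (linear genomes). Returns
# unique (position, strand, mismatches, bulge_type, bulge_size) tuples.
oracle_offtarget <- function(genome, spacer, pam_pattern, max_mm,
                             max_dna, max_rna) {
  n <- nchar(genome$sequence)
  L <- nchar(spacer)
  sp <- chars(spacer)
  Lp <- nchar(pam_pattern)
  out <- list()
  scan_one <- function(seq_chars_vec, strand) {
    ns <- length(seq_chars_vec)
    emit <- function(p, tl, mm, type, size) {
      if (p + tl + Lp - 1L > ns) return()
      if (!iupac_ok(seq_chars_vec[(p + tl):(p + tl + Lp - 1L)], pam_pattern)) return()
      fpos <- if (strand == "+") p else ns - (p + tl - 1L) + 1L
      out[[length(out) + 1L]] <<- data.frame(
        pos = fpos, strand = strand, mm = mm, type = type, size = size,
        stringsAsFactors = FALSE)
    }
    for (p in seq_len(ns)) {
      # ungapped
      if (p + L - 1L <= ns) {
        mm <- sum(seq_chars_vec[p:(p + L - 1L)] != sp)
        if (mm <= max_mm) emit(p, L, mm, "none", 0L)
      }
      # RNA bulge: spacer loses a run of k (target shorter)
      for (k in seq_len(max_rna)) {
        tl <- L - k
        if (p + tl - 1L > ns) next
        for (i in 2:(L - k)) {
          q <- sp[-(i:(i + k - 1L))]
          mm <- sum(seq_chars_vec[p:(p + tl - 1L)] != q)
          if (mm <= max_mm) emit(p, tl, mm, "RNA", k)
        }
      }
      # DNA bulge: target gains a run of k (skipped in comparison)
      for (k in seq_len(max_dna)) {
        tl <- L + k
        if (p + tl - 1L > ns) next
        for (i in 1:(L - 1L)) {
          tgt <- seq_chars_vec[p:(p + tl - 1L)]
          tgt_cmp <- tgt[-((i + 1L):(i + k))]
          mm <- sum(tgt_cmp != sp)
          if (mm <= max_mm) emit(p, tl, mm, "DNA", k)
        }
      }
    }
  }
  scan_one(chars(genome$sequence), "+")
  scan_one(chars(rc(genome$sequence)), "-")
  if (!length(out)) {
    return(data.frame(pos = integer(), strand = character(), mm = integer(),
                      type = character(), size = integer()))
  }
  d <- unique(do.call(rbind, out))
  d[order(d$pos, d$strand, d$mm), , drop = FALSE]
}

# Plain Smith-Waterman DP (linear gap penalty), best local score.
oracle_sw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- chars(a); B <- chars(b)
  na <- length(A); nb <- length(B)
  H <- matrix(0, na + 1L, nb + 1L)
  best <- 0
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      sc <- if (A[i] == B[j]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + sc, H[i, j + 1L] + gap,
                               H[i + 1L, j] + gap)
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# Independent codon tally via seqinr::uco.
oracle_codon_usage <- function(coding_seqs) {
  total <- NULL
  for (s in coding_seqs) {
    u <- seqinr::uco(chars(tolower(s)), index = "eff")
    total <- if (is.null(total)) u else total + u[names(total)]
  }
  counts <- as.integer(total)
  names(counts) <- toupper(names(total))
  counts
}
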