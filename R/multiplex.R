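#' Default parts registry for array assembly
#'
#' Named DNA parts used by [build_array()]. The sgRNA scaffold, direct
#' repeat and tracrRNA are the public SpCas9 sequences; promoter,
#' terminator and the two tRNAs are synthetic placeholder sequences (real
#' constructs should load their own registry with [read_parts_registry()]).
#' tRNA parts end in CCA and deliberately lack a poly-U run.
#'
#' @return named character vector of part sequences with a `roles`
#'   attribute mapping each part to its role.
#' @export
default_parts_registry <- function() {
  parts <- c(
    promoter = "TTGACAATTAATCATCGGCTCGTATAATGTGTGGAATTGTGAGCGG",
    scaffold = paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAA",
                      "CTTGAAAAAGTGGCACCGAGTCGGTGC"),
    terminator = paste0("CTAGCATAACCCCTTGGGGCCTCTAAACGGGTCTTGAGGGGTTTTTTG"),
    dr = "GTTTTAGAGCTATGCTGTTTTGAATGGTCCCAAAAC",
    tracrrna = paste0("GGAACCATTCAAAACAGCATAGCAAGTTAAAATAAGGCTAGTCCGTTAT",
                      "CAACTTGAAAAAGTGGCACCGAGTCGGTGCTTTTTTT"),
    # synthetic tRNA-like parts ending in CCA, no poly-U. trna_thr carries
    # a weak all-A/U 5-bp stem with a 7-nt loop starting 21 nt from the
    # CCA end (a T-arm-like feature); trna_fmet deliberately lacks one.
    trna_thr = paste0("GGCGGCGGCATGCATGCGCGGCATGCGGCG",
                      "TTAAT", "TTCGAAT", "ATTAA", "G", "CCA"),
    trna_fmet = paste0("GGCGGGGTGGAGCAGCCTGGTAGCTCGTCGGGCTCATAACCCGAAG",
                       "GTCGTCGGTTCAAATCCGGCCCCCGCAACCA")
  )
  roles <- c(promoter = "promoter", scaffold = "scaffold",
             terminator = "terminator", dr = "dr", tracrrna = "tracrrna",
             trna_thr = "trna", trna_fmet = "trna")
  attr(parts, "roles") <- roles
  parts
}

#' Read a parts registry from a FASTA file
#'
#' Part roles are taken from a `role=` tag in the FASTA header
#' (`>name role=promoter`), defaulting to the part name.
#'
#' @param path FASTA path.
#' @return named character vector with a `roles` attribute.
#' @export
read_parts_registry <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  nm <- sub("\\s.*$", "", headers)
  role <- ifelse(grepl("role=", headers),
                 sub(".*role=(\\S+).*", "\\1", headers), nm)
  parts <- setNames(as.character(ss), nm)
  attr(parts, "roles") <- setNames(role, nm)
  parts
}

#' Evaluate a pre-tRNA candidate for use in tRNA-sgRNA arrays
#'
#' Applies the sequence-level screen used to pick tRNAs whose maturation
#' releases the fused sgRNAs: (i) the 20-nt 3' trailer must not contain a
#' poly-U run (>= 4 consecutive T/U) that could terminate transcription;
#' (ii) a weak, A/U-rich stem-loop (stem >= 4 bp, loop 3-8 nt) should
#' start roughly 16 nt (window 10-22 nt) back from the CCA 3' end of the
#' mature tRNA -- the T-arm region -- found here by a base-pair
#' maximisation hairpin scan; and
#' (iii) the decoded codon should be in relatively high usage, ranked
#' against a codon-usage table.
#'
#' @param name candidate name, e.g. `"Thr-TGT-1-1"`.
#' @param mature_seq mature tRNA sequence (DNA alphabet, ends in CCA).
#' @param trailer_seq 20-nt 3' pre-tRNA trailer.
#' @param decoded_codon the codon this tRNA decodes (DNA alphabet).
#' @param usage a [compute_codon_usage()] table, for the codon rank.
#' @param polyu_min minimum run of T defining a poly-U tail (default 4).
#' @param stem_window distance window (nt back from the CCA end of the
#'   mature tRNA) where the stem-loop may start (default `c(10, 22)`).
#' @param wobble allow G-T (G-U) pairs in the stem (default `TRUE`).
#' @return list of class `trna_report`: `name`, `has_polyu_trailer`,
#'   `stem_candidates` (data.frame: `position`, `stem_length`,
#'   `loop_length`, `au_fraction`), `codon_usage_rank`, `pass_polyu`,
#'   `pass_stem`, `pass`.
#' @export
evaluate_pre_trna <- function(name, mature_seq, trailer_seq, decoded_codon,
                              usage = NULL, polyu_min = 4L,
                              stem_window = c(10L, 22L), wobble = TRUE) {
  mature_seq <- toupper(gsub("U", "T", mature_seq))
  trailer_seq <- toupper(gsub("U", "T", trailer_seq))
  if (nchar(trailer_seq) != 20L) {
    warning("trailer is ", nchar(trailer_seq), " nt (expected 20)")
  }
  has_cca <- endsWith(mature_seq, "CCA")
  if (!has_cca) warning("mature tRNA does not end in CCA; stem distance skipped")
  has_polyu <- grepl(strrep("T", polyu_min), trailer_seq)

  stems <- if (has_cca) {
    scan_hairpins(mature_seq, min_stem = 4L, loop_range = c(3L, 8L),
                  pos_window = stem_window, wobble = wobble)
  } else {
    data.frame(position = integer(), stem_length = integer(),
               loop_length = integer(), au_fraction = numeric())
  }
  rank <- if (!is.null(usage)) codon_usage_rank(usage, decoded_codon) else NA_integer_
  out <- list(name = name, has_polyu_trailer = has_polyu,
              stem_candidates = stems, codon_usage_rank = rank,
              pass_polyu = !has_polyu, pass_stem = nrow(stems) > 0L)
  out$pass <- out$pass_polyu && out$pass_stem
  class(out) <- "trna_report"
  out
}

#' @exportS3Method base::print
print.trna_report <- function(x, ...) {
  cat(sprintf("<trna_report> %s: polyU=%s, stems=%d, codon rank=%s, pass=%s\n",
              x$name, x$has_polyu_trailer, nrow(x$stem_candidates),
              x$codon_usage_rank, x$pass))
  invisible(x)
}

# Enumerate hairpins in `seq`; `position` of a hairpin is the distance
# from the 3' end of `seq` to the first base of its 5' stem arm (so the
# T-arm of a tRNA sits around position 16-22). Only hairpins whose
# position falls in pos_window are reported; stem >= min_stem contiguous
# pairs, loop length in loop_range; maximal stems only.
scan_hairpins <- function(seq, min_stem = 4L, loop_range = c(3L, 8L),
                          pos_window = c(10L, 22L), wobble = TRUE) {
  ch <- seq_chars(toupper(seq))
  n <- length(ch)
  pairs <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G") |
      (wobble & ((a == "G" & b == "T") | (a == "T" & b == "G")))
  }
  rows <- list()
  # anchor at the loop and grow the stem outward: base j-1-t of the 5' arm
  # pairs with base j+loop+t of the 3' arm
  for (j in 2:n) {
    for (loop in loop_range[1]:loop_range[2]) {
      stem <- 0L
      while (j - 1L - stem >= 1L && j + loop + stem <= n &&
             pairs(ch[j - 1L - stem], ch[j + loop + stem])) {
        stem <- stem + 1L
      }
      if (stem < min_stem) next
      i <- j - stem                      # first base of the 5' arm
      dist3 <- n - i + 1L
      if (dist3 < pos_window[1] || dist3 > pos_window[2]) next
      stem_bases <- ch[c(i:(j - 1L), (j + loop):(j + loop + stem - 1L))]
      rows[[length(rows) + 1L]] <- data.frame(
        position = dist3, stem_length = stem, loop_length = loop,
        au_fraction = mean(stem_bases %in% c("A", "T")))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(position = integer(), stem_length = integer(),
                      loop_length = integer(), au_fraction = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$position, out$loop_length), , drop = FALSE]
}

#' Assemble a multiplex sgRNA expression cassette
#'
#' Three architectures: `msgRNA` repeats a full transcriptional unit
#' (promoter, spacer, scaffold, terminator) per spacer; `mtRNA` is a single
#' unit in which consecutive spacer+scaffold sgRNAs are separated by tRNAs
#' (n-1 tRNAs for n spacers) so tRNA maturation releases the sgRNAs;
#' `mCRISPR` is a native-style CRISPR array (direct repeat and 30-nt
#' spacer, repeated, closed by a repeat) plus a separate tracrRNA unit. In
#' the legacy mCRISPR mode each 30-nt spacer is a 6-nt restriction site +
#' 4 random nt + the 20-nt spacer; the recommended mode uses 30 nt fully
#' homologous to the target (supply 30-nt spacers, or the 20-nt spacer is
#' extended with its annotated 5' context via `spacer5ext`).
#'
#' @param spacers character vector of spacer sequences (5'->3').
#' @param strategy `"msgRNA"`, `"mtRNA"` or `"mCRISPR"`.
#' @param parts parts registry ([default_parts_registry()] or
#'   [read_parts_registry()]).
#' @param seed integer seed for the legacy mCRISPR random 4-mers.
#' @param mcrispr_mode `"legacy"` or `"homologous"`.
#' @param restriction_site 6-nt site used in legacy mCRISPR spacers.
#' @param spacer5ext optional character vector of 10-nt 5' extensions for
#'   `"homologous"` mode when `spacers` are 20 nt.
#' @param trnas names of tRNA parts to interleave (recycled; default: all
#'   parts with role `trna`).
#' @return list of class `array_construct`: `strategy`, `parts`
#'   (data.frame `name`, `role`, `sequence`), `assembled_seq`, `length`,
#'   and for mCRISPR `tracr_unit`.
#' @export
build_array <- function(spacers, strategy = c("msgRNA", "mtRNA", "mCRISPR"),
                        parts = default_parts_registry(), seed = 1L,
                        mcrispr_mode = c("legacy", "homologous"),
                        restriction_site = "GAATTC", spacer5ext = NULL,
                        trnas = NULL) {
  strategy <- match.arg(strategy)
  mcrispr_mode <- match.arg(mcrispr_mode)
  if (length(spacers) < 1L) stop("need at least one spacer")
  spacers <- toupper(spacers)
  roles <- attr(parts, "roles")
  need_part <- function(role) {
    nm <- names(roles)[roles == role]
    if (length(nm) == 0L) stop("parts registry lacks a part with role '", role, "'")
    nm[1]
  }
  plist <- list()
  add <- function(name, role, sequence) {
    plist[[length(plist) + 1L]] <<- data.frame(name = name, role = role,
                                               sequence = sequence,
                                               stringsAsFactors = FALSE)
  }

  if (strategy == "msgRNA") {
    pr <- need_part("promoter"); sc <- need_part("scaffold"); tm <- need_part("terminator")
    for (i in seq_along(spacers)) {
      add(pr, "promoter", parts[[pr]])
      add(paste0("spacer", i), "spacer", spacers[i])
      add(sc, "scaffold", parts[[sc]])
      add(tm, "terminator", parts[[tm]])
    }
  } else if (strategy == "mtRNA") {
    pr <- need_part("promoter"); sc <- need_part("scaffold"); tm <- need_part("terminator")
    if (is.null(trnas)) trnas <- names(roles)[roles == "trna"]
    n_junction <- length(spacers) - 1L
    if (n_junction > 0L && length(trnas) == 0L) {
      stop("mtRNA needs tRNA parts for ", n_junction, " junctions")
    }
    trna_seq <- if (n_junction > 0L) rep(trnas, length.out = n_junction) else character()
    add(pr, "promoter", parts[[pr]])
    for (i in seq_along(spacers)) {
      add(paste0("spacer", i), "spacer", spacers[i])
      add(sc, "scaffold", parts[[sc]])
      if (i <= n_junction) add(trna_seq[i], "trna", parts[[trna_seq[i]]])
    }
    add(tm, "terminator", parts[[tm]])
  } else { # mCRISPR
    pr <- need_part("promoter"); dr <- need_part("dr"); tm <- need_part("terminator")
    tr <- need_part("tracrrna")
    sp30 <- if (mcrispr_mode == "legacy") {
      rnd <- withr::with_seed(seed, vapply(seq_along(spacers), function(i)
        paste(sample(c("A", "C", "G", "T"), 4L, replace = TRUE), collapse = ""),
        character(1)))
      paste0(restriction_site, rnd, spacers)
    } else {
      if (all(nchar(spacers) == 30L)) spacers
      else if (!is.null(spacer5ext)) paste0(toupper(spacer5ext), spacers)
      else stop("homologous mCRISPR mode needs 30-nt spacers or spacer5ext")
    }
    add(pr, "promoter", parts[[pr]])
    for (i in seq_along(sp30)) {
      add(dr, "dr", parts[[dr]])
      add(paste0("spacer", i), "spacer", sp30[i])
    }
    add(dr, "dr", parts[[dr]])
    add(tm, "terminator", parts[[tm]])
  }
  pdf <- do.call(rbind, plist)
  out <- list(strategy = strategy, parts = pdf,
              assembled_seq = paste(pdf$sequence, collapse = ""),
              length = sum(nchar(pdf$sequence)))
  if (strategy == "mCRISPR") {
    tr <- need_part("tracrrna"); pr <- need_part("promoter"); tm <- need_part("terminator")
    tru <- data.frame(name = c(pr, tr, tm),
                      role = c("tracr_promoter", "tracrrna", "tracr_terminator"),
                      sequence = c(parts[[pr]], parts[[tr]], parts[[tm]]),
                      stringsAsFactors = FALSE)
    out$tracr_unit <- tru
  }
  class(out) <- "array_construct"
  out
}

#' @exportS3Method base::print
print.array_construct <- function(x, ...) {
  cat(sprintf("<array_construct> %s: %d parts, %d nt\n",
              x$strategy, nrow(x$parts), x$length))
  invisible(x)
}

#' Write an array construct to FASTA
#'
#' One record for the assembled cassette (and one for the tracrRNA unit of
#' mCRISPR constructs), plus one record per part when `parts = TRUE`.
#'
#' @param construct an [build_array()] result.
#' @param path output FASTA path.
#' @param parts also emit the individual parts.
#' @return `path`, invisibly.
#' @export
write_array_fasta <- function(construct, path, parts = FALSE) {
  seqs <- c(setNames(construct$assembled_seq,
                     paste0(construct$strategy, "_cassette")))
  if (!is.null(construct$tracr_unit)) {
    seqs <- c(seqs, tracr_unit = paste(construct$tracr_unit$sequence, collapse = ""))
  }
  if (parts) {
    pn <- sprintf("%s_part%02d_%s", construct$strategy,
                  seq_len(nrow(construct$parts)), construct$parts$role)
    seqs <- c(seqs, setNames(construct$parts$sequence, pn))
  }
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
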