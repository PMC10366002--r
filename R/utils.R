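#' @importFrom stats setNames
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] that keeps plain
#' character vectors in and out; `N` is preserved.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split one sequence into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Does the base `b` (A/C/G/T/N) satisfy the IUPAC code `code`?
# N in the subject never matches anything (design rule: ambiguous bases
# never match a PAM and never qualify as editable C).
iupac_match <- function(b, code) {
  b %in% IUPAC_SETS[[code]]
}

# Vectorised check that each window of `chars` starting at `starts`
# matches the IUPAC pattern (character vector of codes).
match_iupac_at <- function(chars, starts, pattern_codes) {
  ok <- rep(TRUE, length(starts))
  for (j in seq_along(pattern_codes)) {
    allowed <- IUPAC_SETS[[pattern_codes[j]]]
    ok <- ok & chars[starts + j - 1L] %in% allowed
  }
  ok
}

# 1-based circular index into a genome of length n.
wrap_pos <- function(pos, n) ((pos - 1L) %% n) + 1L

# Substring with optional circular wrap-around.
genome_substr <- function(sequence, start, end, circular = FALSE) {
  n <- nchar(sequence)
  if (start >= 1L && end <= n) return(substr(sequence, start, end))
  if (!circular) stop("interval [", start, ",", end, "] outside linear genome")
  idx <- wrap_pos(seq.int(start, end), n)
  paste(seq_chars(sequence)[idx], collapse = "")
}

# All non-empty subsets of a vector, ordered by size then lexicographic.
# (combn() is fed indices: a length-1 numeric x would otherwise be taken
# as seq_len(x).)
nonempty_subsets <- function(x) {
  if (length(x) == 0L) return(list())
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    cmb <- utils::combn(seq_along(x), k, simplify = FALSE)
    out <- c(out, lapply(cmb, function(i) x[i]))
  }
  out
}

# Random DNA with a given GC content, using the current RNG stream.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
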