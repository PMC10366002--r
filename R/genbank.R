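# Minimal GenBank flat-file I/O.
#
# Covers the subset of the format this package reads and writes: a single
# LOCUS per file, topology (linear/circular) from the LOCUS line, CDS
# features with location forms `a..b`, `complement(a..b)` and
# `join(a..b,c..d)` (origin wrap), qualifiers /locus_tag and /pseudo, and
# the ORIGIN sequence block. Anything else is ignored on read.

parse_genbank_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    rng <- do.call(rbind, lapply(parts, function(p) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    }))
    # origin-wrapping join: start of first segment, end of last
    return(list(start = rng[1, 1], end = rng[nrow(rng), 2], strand = strand,
                n_segments = nrow(rng)))
  }
  se <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  if (length(se) == 1L) se <- c(se, se)
  list(start = se[1], end = se[2], strand = strand, n_segments = 1L)
}

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  locus <- lines[locus_i[1]]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(grepl("^circular$", toks, ignore.case = TRUE))
  vi <- grep("^VERSION", lines)
  if (length(vi)) {
    vt <- strsplit(trimws(lines[vi[1]]), "\\s+")[[1]]
    if (length(vt) >= 2) id <- vt[2]
  }

  # sequence
  oi <- grep("^ORIGIN", lines)
  if (length(oi) == 0L) stop("GenBank file has no ORIGIN block: ", path)
  end_i <- grep("^//", lines)
  end_i <- end_i[end_i > oi[1]][1]
  if (is.na(end_i)) end_i <- length(lines) + 1L
  seq_lines <- lines[(oi[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  # features
  fi <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fi)) {
    block <- lines[(fi[1] + 1L):(oi[1] - 1L)]
    # a new feature starts at column 6 with a non-space key
    starts <- grep("^ {5}\\S", block)
    for (k in seq_along(starts)) {
      from <- starts[k]
      to <- if (k < length(starts)) starts[k + 1L] - 1L else length(block)
      key <- trimws(substr(block[from], 1, 20))
      if (key != "CDS") next
      body <- block[from:to]
      # location may continue over lines until the first qualifier
      qual_i <- grep("^ {21}/", body)
      loc_end <- if (length(qual_i)) qual_i[1] - 1L else length(body)
      loc <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", body[1]),
                            if (loc_end >= 2) trimws(body[2:loc_end]))), collapse = "")
      quals <- body[grep("^ {21}/", body)]
      tag <- sub('^.*?/locus_tag="([^"]*)".*$', "\\1",
                 grep("/locus_tag=", quals, value = TRUE)[1])
      if (is.na(tag) || !length(tag)) tag <- paste0("CDS_", length(feats) + 1L)
      pseudo <- any(grepl("^\\s*/pseudo\\s*$", quals))
      pl <- parse_genbank_location(loc)
      feats[[length(feats) + 1L]] <- data.frame(
        id = tag, start = pl$start, end = pl$end, strand = pl$strand,
        pseudo = pseudo, stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  annotated_genome(id, sequence, features, circular = circular)
}

write_genbank <- function(genome, path) {
  n <- genome_length(genome)
  topo <- if (genome$circular) "circular" else "linear"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s BCT %s",
                     genome$id, n, topo, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", genome$id), con)
  writeLines(sprintf("VERSION     %s", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  ft <- genome$features
  for (i in seq_len(nrow(ft))) {
    loc <- if (ft$end[i] >= ft$start[i]) {
      sprintf("%d..%d", ft$start[i], ft$end[i])
    } else {
      sprintf("join(%d..%d,1..%d)", ft$start[i], n, ft$end[i])
    }
    if (ft$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf('                     /locus_tag="%s"', ft$id[i]), con)
    if (ft$pseudo[i]) writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$sequence)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
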