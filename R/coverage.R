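#' Targeting space of a PAM on a genome
#'
#' Number of STOP-capable protospacers in the first `first_fraction` of
#' their CDS, genome-wide.
#'
#' @inheritParams design_knockouts
#' @param counting `"pair"` counts (protospacer site, CDS) pairs (a site
#'   overlapping two CDSs counts twice); `"site"` counts distinct
#'   protospacer sites.
#' @return integer count.
#' @export
targeting_space <- function(genome, pam, window = editing_window(),
                            first_fraction = 0.75,
                            counting = c("pair", "site"), ...) {
  counting <- match.arg(counting)
  hits <- design_knockouts(genome, pam, window, first_fraction, ...)
  count_hits(hits, counting)
}

count_hits <- function(hits, counting = c("pair", "site")) {
  counting <- match.arg(counting)
  if (counting == "pair") return(nrow(hits))
  nrow(unique(hits[c("genome_start", "genome_end", "protospacer_strand")]))
}

#' Genomic coverage of a PAM
#'
#' Percentage of non-pseudo CDSs carrying at least one STOP-capable
#' protospacer.
#'
#' @inheritParams targeting_space
#' @return percentage in `[0, 100]`.
#' @export
genomic_coverage <- function(genome, pam, window = editing_window(),
                             first_fraction = 0.75, ...) {
  total <- nrow(extract_cds_records(genome))
  if (total == 0L) stop("genome has no non-pseudo CDS")
  hits <- design_knockouts(genome, pam, window, first_fraction, ...)
  100 * length(unique(hits$cds_id)) / total
}

#' Combined coverage of several PAMs
#'
#' Coverage of the union of covered-CDS sets across the supplied PAM
#' specifications.
#'
#' @param genome an [annotated_genome()].
#' @param pam_set list of [pam_spec()] objects.
#' @inheritParams targeting_space
#' @return percentage in `[0, 100]`.
#' @export
combined_coverage <- function(genome, pam_set, window = editing_window(),
                              first_fraction = 0.75, ...) {
  if (length(pam_set) == 0L) stop("pam_set must contain at least one PAM")
  if (inherits(pam_set, "pam_spec")) pam_set <- list(pam_set)
  total <- nrow(extract_cds_records(genome))
  if (total == 0L) stop("genome has no non-pseudo CDS")
  covered <- unique(unlist(lapply(pam_set, function(p) {
    design_knockouts(genome, p, window, first_fraction, ...)$cds_id
  })))
  100 * length(covered) / total
}

#' Targeting-space and coverage report across PAM variants
#'
#' One row per PAM (and per requested union) with the targeting space,
#' covered/total CDS counts and coverage percentage; the modelling
#' parameters are recorded as attributes.
#'
#' @param genome an [annotated_genome()].
#' @param pam_list list of [pam_spec()] objects.
#' @param unions optional list of integer/character vectors naming members
#'   of `pam_list` to combine (e.g. `list(c("NG", "NAA"))`).
#' @inheritParams targeting_space
#' @return `data.frame` with columns `pam`, `pattern`, `targeting_space`,
#'   `covered_cds`, `total_cds`, `coverage_pct`.
#' @export
pam_comparison_report <- function(genome, pam_list, unions = NULL,
                                  window = editing_window(),
                                  first_fraction = 0.75,
                                  counting = c("pair", "site"), ...) {
  counting <- match.arg(counting)
  if (inherits(pam_list, "pam_spec")) pam_list <- list(pam_list)
  names(pam_list) <- vapply(pam_list, `[[`, character(1), "name")
  total <- nrow(extract_cds_records(genome))
  if (total == 0L) stop("genome has no non-pseudo CDS")
  per_pam <- lapply(pam_list, function(p) {
    design_knockouts(genome, p, window, first_fraction, ...)
  })
  rows <- lapply(names(pam_list), function(nm) {
    h <- per_pam[[nm]]
    data.frame(pam = nm, pattern = pam_list[[nm]]$pattern,
               targeting_space = count_hits(h, counting),
               covered_cds = length(unique(h$cds_id)), total_cds = total,
               coverage_pct = round(100 * length(unique(h$cds_id)) / total, 2),
               stringsAsFactors = FALSE)
  })
  for (u in unions) {
    members <- if (is.character(u)) u else names(pam_list)[u]
    hs <- per_pam[members]
    covered <- unique(unlist(lapply(hs, `[[`, "cds_id")))
    space <- sum(vapply(hs, count_hits, integer(1), counting = counting))
    rows[[length(rows) + 1L]] <- data.frame(
      pam = paste(members, collapse = "+"),
      pattern = paste(vapply(pam_list[members], `[[`, character(1), "pattern"),
                      collapse = "+"),
      targeting_space = space, covered_cds = length(covered),
      total_cds = total,
      coverage_pct = round(100 * length(covered) / total, 2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "parameters") <- list(window = unclass(window),
                                  first_fraction = first_fraction,
                                  counting = counting)
  out
}

#' Per-gene protospacer counts
#'
#' Number of STOP-capable protospacers found in each of the named CDSs.
#'
#' @inheritParams targeting_space
#' @param cds_ids locus tags to tabulate (default: all covered CDSs).
#' @return named integer vector.
#' @export
per_gene_counts <- function(genome, pam, cds_ids = NULL,
                            window = editing_window(), first_fraction = 0.75,
                            ...) {
  hits <- design_knockouts(genome, pam, window, first_fraction, ...)
  tb <- table(hits$cds_id)
  if (is.null(cds_ids)) return(setNames(as.integer(tb), names(tb)))
  out <- setNames(integer(length(cds_ids)), cds_ids)
  found <- intersect(cds_ids, names(tb))
  out[found] <- as.integer(tb[found])
  out
}

#' Convention grid for matching published targeting-space figures
#'
#' The counting rule behind a published targeting-space/coverage figure is
#' rarely fully specified. This runner evaluates every combination of
#' window bounds, 75%-rule anchor, site-vs-pair counting and edit-subset
#' policy, and reports the modelled numbers for each, so the configuration
#' reproducing a published set of numbers can be identified and adopted as
#' the default.
#'
#' @param genome an [annotated_genome()].
#' @param pam_list list of [pam_spec()] objects.
#' @param unions passed to [pam_comparison_report()].
#' @param windows list of [editing_window()]s to try.
#' @param anchors,countings,subset_modes character vectors of options.
#' @param first_fraction leading-CDS-fraction rule.
#' @return `data.frame`: one row per (configuration, PAM row) with the
#'   configuration columns prepended.
#' @export
convention_grid <- function(genome, pam_list, unions = NULL,
                            windows = list(editing_window(-19, -16),
                                           editing_window(-20, -16)),
                            anchors = c("stop", "protospacer"),
                            countings = c("pair", "site"),
                            subset_modes = c("any", "single"),
                            first_fraction = 0.75) {
  rows <- list()
  for (w in windows) for (a in anchors) for (co in countings) for (sm in subset_modes) {
    rep <- pam_comparison_report(genome, pam_list, unions = unions, window = w,
                                 first_fraction = first_fraction,
                                 counting = co, anchor = a, subset_mode = sm)
    cfg <- data.frame(window = sprintf("%d..%d", w$from_pos, w$to_pos),
                      anchor = a, counting = co, subset_mode = sm,
                      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- cbind(cfg[rep(1L, nrow(rep)), , drop = FALSE], rep)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
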