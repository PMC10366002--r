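---
title: "Designing STOP-codon base-editor guides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing STOP-codon base-editor guides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bestop)
```

## The design problem

Cytosine base editors (CBEs) such as Target-AID convert C to T on the
protospacer strand within a narrow, PAM-relative *editing window*,
without cutting the DNA. The cleanest way to knock a bacterial gene out
with a CBE is a nonsense edit: pick a protospacer whose window cytosines,
once deaminated, turn an in-frame codon into TAA, TAG or TGA. On the
sense strand the productive wild-type codons are CAA, CAG and CGA; on the
antisense strand the editable C sits opposite a coding-strand G, so the
only productive coding codon is TGG (via CCA on the protospacer strand,
whose single and double edits give TGA, TAG and TAA).

`bestop` implements this design calculus genome-wide: PAM scanning on
both strands, enumeration of stop-producing edit subsets, aggregation
into targeting-space and coverage statistics across Cas9 PAM variants,
bulge-aware off-target search with variant association, pre-tRNA
screening and multiplex cassette assembly, and a synthetic-genome
generator that makes every stage testable without downloads.

## Editing window and edit enumeration

Positions are counted PAM-relative: the PAM-proximal protospacer base is
-1, so a 20-nt spacer spans -20..-1. The default window is **-19..-16**,
the rule under which the genome-wide counts this package reports are
computed; a wider -20..-16 window (sometimes quoted for Target-AID) is
selectable via `editing_window(-20, -16)` and is part of the convention
grid below.

`stop_edits_for_protospacer()` and `design_knockouts()` enumerate every
non-empty subset of window positions carrying a C on the protospacer
strand, apply C->T (equivalently G->A on the coding strand for antisense
guides), and keep each subset that leaves a stop codon in frame. Subsets
matter: a CCA opposite TGG yields three distinct stop outcomes, and
genotyping tables of real CBE experiments show both single and double
edits. A `subset_mode = "single"` restriction exists for sensitivity
analysis. A subset spanning two codons is credited to whichever
overlapped codon becomes a stop; the stop codon must lie wholly inside
the CDS, while the PAM and parts of the protospacer may hang outside it.

Guide quality follows the empirical editing-outcome guidance:
exactly one window C at -18 or -19 is `clean`; two or more window Cs is
`multi_C` (each cell lineage in a colony can immunise itself by editing a
different C, producing mixed colonies); a lone C at -17 or -16 is
`window_edge` (such positions are rarely edited well). Ambiguous bases
(`N`) never match a PAM and never count as editable.

## Targeting space, coverage and the convention grid

For a PAM specification, the **targeting space** is the number of
STOP-capable protospacers whose would-be stop codon starts within the
first 75% of its CDS, and **genomic coverage** is the percentage of
non-pseudo CDSs with at least one such protospacer;
`combined_coverage()` takes the union of covered-CDS sets across PAMs.
Published versions of such figures rarely pin down every counting
convention, so `convention_grid()` evaluates all combinations of window
bounds (-19..-16 vs -20..-16), the 75%-rule anchor (stop codon vs
protospacer start), site vs (site, CDS)-pair counting, and any-subset vs
single-C qualification, so that the configuration reproducing a given
set of published numbers can be identified empirically and adopted. The
package defaults are: window -19..-16, stop-codon anchor, pair counting,
any subset. Percentages are reported to two decimals.

Coordinates are 1-based inclusive internally, matching the R/Bioconductor
convention and the way genomic positions are printed in annotation and
variant tables; BED output converts to 0-based half-open on write. CDS
features whose span is not a multiple of three (frameshifted or joined
pseudogenes) are flagged pseudo and excluded from design and codon-usage
computations, which keeps the codon arithmetic well-defined.

## Off-target search

`search_offtargets()` follows the gapped-seed semantics of bulge-aware
off-target scanners: a query expands into the ungapped spacer, every
pattern with a contiguous interior deletion of up to `max_rna_bulge`
bases (RNA bulge: the spacer has an extra base), and every pattern with a
contiguous interior run of up to `max_dna_bulge` `N` wildcards (DNA
bulge: the target has an extra base). Terminal bulges are excluded as
degenerate (equivalent to a shorter or shifted match). Each pattern is
slid over both strands with vectorised integer-code comparison; a site is
reported when the mismatch count is within the limit *and* the PAM
pattern matches immediately 3' of the aligned target. `"primary"` mode
keeps the best alignment per (position, strand) — fewest mismatches, then
smallest bulge, then bulge type none < RNA < DNA; `"raw"` mode keeps
every (position, strand, pattern) combination, the counting convention
needed for site-count parity with the original tools. By default the PAM
used for off-target scanning is the PAM of the editor that used the
spacer; that choice (like the raw-mode parity counting) is configurable
because published methods sections rarely state either.

Variant association uses an inclusive 50-nt rule: the distance between a
variant and a site is the minimum distance to the site's occupied
interval (0 inside), and an association is emitted at distance <= 50.
For variants the gapped search leaves unexplained,
`local_align_fallback()` runs a Smith-Waterman local alignment of the
spacer (both orientations) against the 41-nt wild-type context of the
variant, with match +1, mismatch -1, gap -2 and a report threshold of 11
aligned matches. The original screen used an interactive alignment
viewer with no stated scoring scheme, so these values are explicit,
configurable choices here.

## Pre-tRNA screening and multiplex cassettes

Fusing sgRNAs to tRNAs lets one transcriptional unit release several
guides through host tRNA maturation. `evaluate_pre_trna()` applies the
sequence-level screen used to choose such tRNAs, in decreasing order of
importance: a weak, A/U-rich stem-loop (stem >= 4 bp, loop 3-8 nt)
starting 10-22 nt back from the CCA 3' end of the mature tRNA (the T-arm
region; "approximately 16 nt" is operationalised as that interval); no
poly-U run (>= 4 consecutive U) in the 20-nt pre-tRNA trailer, which
could terminate transcription; and a decoded codon of relatively high
usage, ranked against a `compute_codon_usage()` table so that guide
processing does not deplete a rare tRNA pool. The hairpin scan is a
base-pair-maximisation heuristic (Watson-Crick plus G-U wobble) — a
deliberate sequence-level stand-in for thermodynamic RNA folding, chosen
so the screen is deterministic and dependency-free; a thermodynamic
folder can be substituted by feeding its hairpin calls into the same
report structure.

`build_array()` assembles the three multiplexing architectures: `msgRNA`
(one promoter/spacer/scaffold/terminator unit per guide), `mtRNA` (one
promoter, spacer+scaffold sgRNAs interleaved with n-1 tRNAs, one
terminator) and `mCRISPR` (promoter, alternating direct repeats and
30-nt spacers closed by a terminal repeat, plus a separate tracrRNA
unit). Legacy mCRISPR spacers are 6-nt restriction site + 4 seeded-random
nt + the 20-nt spacer — the historical cloning-driven layout, which
later proved inadvisable — while the recommended mode takes 30 nt fully
homologous to the target. The scaffold, direct repeat and tracrRNA
defaults are the public SpCas9 sequences; promoter, terminator and tRNA
parts are synthetic placeholders (real constructs carry plasmid-specific
parts that are not published), so cassette lengths are only meaningful as
comparisons within one registry — the tRNA-fusion cassette is always the
shorter of the two sgRNA-scaffold architectures, which is the property
the package asserts.

## The synthetic-genome generator

`generate_annotated_genome()` emulates the relevant features of a small
acetogen chromosome: a circular replicon, AT-rich background (default GC
0.31), 30-1500 nt genes (default mean 900, sd 250 nt, forced to a
multiple of three) on both strands with intergenic spacers (mean 120 nt),
every CDS a clean ORF (ATG start, single terminal stop, no internal
in-frame stop). It does **not** emulate operon structure, realistic codon
bias, repeated elements or mobile DNA — so passing tests demonstrate the
correctness of the design calculus, not performance on repeat-rich real
genomes, where off-target counts in particular are dominated by repeat
content.

Planting functions rewrite codon-aligned regions so ground truth is
exact: `plant_stop_protospacer()` embeds a protospacer+PAM whose window
C set is known (single C for sense CAA->TAA, the double-C CCA/TGG case
for antisense), using an edit-free filler alphabet so the rewrite cannot
create stops, frameshifts or additional qualifying guides inside the
rewritten stretch; `plant_offtarget_site()` writes a target with an
exact mismatch/bulge profile into intergenic space (>= 25 nt clear of
CDS boundaries) and re-verifies the profile by exhaustive search,
retrying up to 100 times before failing rather than degrading silently;
`generate_variants()` places SNPs at controlled distances including the
50/51-nt boundary pair, with the association expectation evaluated
against *all* planted sites (a variant planted 51 nt from one site may
legitimately sit within 50 nt of another). All generation is
deterministic given a seed.

## Numerical and testing choices

Degenerate inputs are defined, not guessed: zero CDSs give an empty
design with a warning (an error for coverage percentages, which would be
0/0); codons containing N are excluded from usage tables; an empty PAM
set is an argument error. Ties in hit ordering break by genome start,
then `+` before `-`. The fraction rule is inclusive (`<=`).

The test suite checks the implementation against independent oracles
that share no code with it: a character-by-character PAM scanner; a
knockout-design oracle that applies each candidate edit to the whole
genome, re-extracts every CDS and re-translates; an exhaustive
per-position bulge enumerator for off-target search; a hand-rolled
Smith-Waterman for the alignment fallback; and `seqinr::uco` for codon
tallies. Oracle-equality tests run on 1-4 kb synthetic genomes with 3-5
genes, and the acceptance script models a 40-gene (~40 kb) replicon —
sizes chosen so the exhaustive oracles (which are quadratic-ish by
design) stay comfortably inside a test run while still exercising both
strands, both orientations and all PAM classes. Genome-scale checks
against the published *C. autoethanogenum* figures require a local copy
of the CP012395.1 GenBank file (see `tests/testthat/helper-acceptance.R`
for the search paths); the package cannot redistribute the 4.6-Mb
chromosome.

## Known limitations

- Editing *efficiency* is out of scope: the package predicts which edits
  are possible, not their rates or allele frequencies; hit quality labels
  are the only efficiency-adjacent output.
- The pure-R off-target scanner is comfortable on bacterial genomes up to
  a few Mb at moderate limits, but the full (9 mismatches, 2+2 bulge)
  parity scan of a 4.6-Mb genome is at the edge of what is practical
  without compiled code.
- Insertion-containing observed alleles (duplication-type edits seen in
  some genotyping traces) are not modelled; prediction scope is
  substitutions only.
- The GenBank reader covers the single-record, CDS-centric subset of the
  format that this pipeline reads and writes; exotic location forms
  beyond `complement()` and origin-wrapping `join()` are ignored.
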