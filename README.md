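# bestop

Design and genome-wide modelling of STOP-codon-introducing base-editor
guides for bacteria.

Cytosine base editors (CBEs, e.g. Target-AID) convert C→T on the
protospacer strand within a PAM-relative editing window, without a
double-strand break — which makes them attractive for organisms that lack
efficient recombination-based editing, such as the industrial acetogen
*Clostridium autoethanogenum*. The cleanest CBE knockout is a nonsense
edit: a guide whose window cytosines, once deaminated, turn an in-frame
codon into TAA, TAG or TGA. With the window at positions −19..−16 from
the PAM (−1 = PAM-proximal base), the productive wild-type codons are CAA,
CAG and CGA on the sense strand, and TGG on the antisense strand (edited
via CCA on the protospacer strand: the single and double C→T edits give
TGA, TAG and TAA respectively).

`bestop` implements this design calculus end to end, for anyone designing
CBE knockouts in annotated bacterial genomes or evaluating which Cas9 PAM
variant (NGG, NG, NAA, or any IUPAC pattern) to build an editor around:

- **`design_knockouts()`** — scan both strands for PAM sites and report
  every protospacer with a STOP-producing window-C edit set in the first
  75% of its CDS, with a quality label (`clean` / `multi_C` /
  `window_edge`) following empirical guide-selection guidance.
- **`targeting_space()` / `genomic_coverage()` / `combined_coverage()` /
  `pam_comparison_report()`** — genome-wide counts of STOP-capable
  protospacers and the percentage of CDSs each PAM can knock out, plus
  PAM-set unions; `convention_grid()` identifies the counting convention
  behind a published figure.
- **`search_offtargets()` / `associate_variants()` /
  `local_align_fallback()`** — bulge-aware off-target search (mismatches
  plus DNA/RNA bulges, Cas-Offinder-style semantics), proximity
  association of observed SNPs within 50 nt, and a Smith-Waterman
  fallback matcher for what the gapped search misses.
- **`evaluate_pre_trna()` / `build_array()`** — sequence-level pre-tRNA
  screening (poly-U trailer, weak A/U-rich stem-loop near the CCA end,
  codon-usage rank) and assembly of msgRNA, mCRISPR and tRNA-sgRNA
  (mtRNA) multiplex cassettes.
- **`generate_annotated_genome()` / `plant_stop_protospacer()` /
  `plant_offtarget_site()` / `generate_variants()`** — a synthetic
  bacterial-genome generator with planted, exactly-known ground truth, so
  every stage of the pipeline is testable without downloads.

Standard formats are supported throughout: GenBank flat files, FASTA +
GFF3, BED6, TSV/JSON hit dumps, and VCF for variants.

## Worked example

```r
library(bestop)

res  <- generate_annotated_genome(synthetic_genome_spec(n_genes = 12), seed = 101)
g    <- res$genome
g
#> <annotated_genome> SYNB01: 12,717 bp, circular, 12 CDS (0 pseudo)

hits <- design_knockouts(g, pam_spec("NG"))
head(hits[c("cds_id", "protospacer_seq", "genome_start",
            "protospacer_strand", "wt_codon", "mutant_codon", "quality")], 4)
#>     cds_id      protospacer_seq genome_start protospacer_strand wt_codon mutant_codon quality
#> 1 SYN_0001 tcaattttacaggaaatata          217                  +      CAA          TAA   clean
#> 2 SYN_0001 atcaagcgattcatattcta          339                  +      CAA          TAA   clean
#> 3 SYN_0001 ccaagatgaaaaataccagg          570                  -      TGG          TAG   clean
#> 4 SYN_0001 acccaagatgaaaaatacca          572                  -      TGG          TAG multi_C
```

Each row is one (protospacer, CDS) pair: the guide sequence 5'→3' on the
protospacer strand, the codon its window edit destroys and the stop it
creates, and the quality label (`clean` = a single window C at −18/−19,
the recommended kind of guide; `multi_C` guides risk mixed colonies).

```r
pam_comparison_report(g, list(pam_spec("NGG"), pam_spec("NG"), pam_spec("NAA")),
                      unions = list(c("NG", "NAA")))
#>      pam pattern targeting_space covered_cds total_cds coverage_pct
#> 1    NGG     NGG              19           9        12           75
#> 2     NG      NG              81          12        12          100
#> 3    NAA     NAA              62          12        12          100
#> 4 NG+NAA  NG+NAA             143          12        12          100
```

The relaxed-PAM editors dominate the canonical NGG editor in targeting
space and coverage — on this small synthetic replicon as on real genomes.
The antisense TGG logic in isolation:

```r
stop_edits_for_protospacer("ctccagtcaggtgttgtgca", "antisense", frame_offset = 0)
#>   edited_offsets codon_index wt_codon mutant_codon stop_triplet
#> 1            -17           5      TGG          TAG          TAG
#> 2            -18           5      TGG          TGA          TGA
#> 3        -18,-17           5      TGG          TAA          TAA
```

## Analysis workflow

The `analysis/` scripts are thin, numbered drivers over the package that
reproduce the full pipeline on a simulated study genome, writing their
tables under `results/`:

```sh
Rscript analysis/01_simulate_genome.R    # genome + planted ground truth
Rscript analysis/02_targeting_space.R    # PAM comparison, convention grid
Rscript analysis/03_offtarget_screen.R   # bulge-aware search + SNP association
Rscript analysis/04_multiplex_arrays.R   # tRNA screen, cassette assembly
```

Step 2 also runs the genome-wide report on the real chromosome when a
local CP012395.1 GenBank copy is available (`options(bestop.genome = ...)`).

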