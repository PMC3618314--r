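---
title: "Stage-transition expression motifs in staged palatal RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-transition expression motifs in staged palatal RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmotif)
```

## The model

Palatogenesis in the mouse runs through shelf elevation (E14.5), adhesion
with formation of the midline epithelial seam (E15.5), and fusion (E16.5).
TGFβ3-null (`hom`) embryos fail at fusion; heterozygotes (`het`) are
phenotypically normal. The analysis this package implements treats each
gene's expression trajectory over the two transitions E14.5→E15.5 and
E15.5→E16.5 as a categorical *motif* and compares motif membership across
genotypes.

The trajectory is computed per gene and genotype:

1. **Aggregate.** Replicate FPKM columns of a (genotype, stage) cell are
   averaged. The default scheme (`mean_all`) is the arithmetic mean over all
   replicate columns; `mean_bio_of_tech` averages technical replicates
   within each biological replicate first. The two coincide for balanced
   designs, which is why the choice is configuration rather than doctrine —
   the upstream quantification this emulates reported condition-level
   abundances and never specified a scheme.
2. **Transform.** Each mean is mapped to `round(log10(FPKM + 1), 2)`. The
   pseudocount keeps zero-FPKM genes defined; the rounding to two decimals
   fixes the working precision of the entire analysis. Rounding is standard
   half-away-from-zero, not ceiling: a ceiling rule would bias every value
   upward, and "rounded to d places" in the source methodology is read as
   ordinary rounding. Values are stored rounded and differenced afterwards,
   so the decision threshold is expressed in the same rounded currency.
3. **Call directions.** With fold-change threshold FC (default 2.0), the
   transformed threshold is `round(log10 FC, 2)` = 0.30. A transition is
   `up` when the later value exceeds the earlier by at least 0.30, `down`
   symmetrically, else `unchanged`. The boundary is inclusive ("FC ≥ 2").
   Because rounded values are exact hundredths, comparisons are made with a
   1e-9 guard so binary floating point cannot flip an exact-boundary call.
   Note the semantics: thresholding differences of log10(FPKM+1) means the
   ratio tested is `(b+1)/(a+1)`, not `b/a`. A raw-ratio mode
   (`fc_config(on_raw = TRUE)`) is provided for comparison and is
   non-default; with a zero denominator it calls regulation whenever the
   numerator is positive.
4. **Assign the motif.** The ordered pair of calls maps bijectively onto
   nine codes: p1 unchanged–unchanged, p2 up–unchanged, p3 unchanged–up,
   p4 up–down, p5 up–up, p6 down–unchanged, p7 down–up, p8 unchanged–down,
   p9 down–down. The map is total: every profile receives exactly one code.

Two set operations carry the biology. `unique_pattern_genes()` extracts
genes holding a motif in a target genotype but not in a reference (with
target `hom`, motif p1, reference `het`: genes suspiciously flat in the
knockout while regulated in the normal heterozygote — the candidate set).
`first_up_then_down()` returns p4 membership, the motif of transcripts
needed transiently around seam degradation.

A useful structural fact, asserted in the tests: reversing the stage order
maps a motif (d1, d2) to (flip d2, flip d1), which on codes is the
involution p1↔p1, p2↔p8, p3↔p6, p4↔p4, p5↔p9, p7↔p7.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `fc` | 2.0 | ratio | the conventional fold-change cut; must be > 1 |
| `decimals` | 2 | decimal places | precision of the transformed values and of the derived threshold (0.30) |
| `inclusive` | TRUE | — | "FC ≥ 2" includes the boundary |
| aggregation `scheme` | `mean_all` | — | balanced designs make the alternatives equal |
| QC `min_r` | 0.9 | correlation | advisory gate; the QC contract reports r but prescribes no cut, so the default is a deliberately loose guard |

The threshold is deliberately *not* configurable independently of `fc`:
`log_delta` is always `round(log10 fc, decimals)`, keeping the two views of
the same cut consistent.

## Replicate QC

`replicate_concordance()` computes Pearson r on **unrounded** log10(FPKM+1)
for every replicate pair within a (genotype, stage) cell — columns differing
in biological replicate are biological pairs, columns sharing it technical
pairs. Rounding is a classifier concern; QC uses the full-precision
transform. Two-tailed p-values come from the t distribution on
`n_genes − 2` degrees of freedom and are annotations only: no
multiple-testing correction is applied because none is part of the QC
contract. Cross-stage correlations are not QC and are never enumerated.
Degenerate inputs are handled explicitly: a zero-variance column yields
`r = NA` (reported, not dropped), and cells with fewer than three genes are
skipped with a warning.

## The synthetic-data generator

`simulate_experiment()` emulates the study design so that every pipeline
stage is testable without any download: 3 genotypes × 3 stages × 2
biological × 2 technical replicates = 36 samples. Per gene and genotype a
baseline `b ~ Normal(1.5, 1.0)` on the log10 scale spans the FPKM dynamic
range from ~0 to beyond 10,000; stage means are `b`, `b + s1`,
`b + s1 + s2` with shifts of ±0.60 (twice the decision threshold) or 0
realizing the planted motif; each replicate observation is
`10^(mean + ε) − 1` with `ε ~ Normal(0, 0.04)`, clipped at zero.

Design choices worth stating:

* **Noise is lognormal on the analysis scale**, not negative-binomial at
  the count level. The pipeline consumes FPKM and classifies on
  log10(FPKM+1); modelling noise on that scale is the simplest model that
  exercises every code path. Count-level simulation with gene-length and
  library-size effects is an extension point, not implemented.
* **Baselines are clamped so every planted stage mean is non-negative.**
  Plain truncation of the baseline alone would let a planted downward step
  push a stage mean below zero, where the zero-clip on FPKM would silently
  erase the planted motif; clamping to the profile minimum preserves the
  truth labels the recovery tests score against.
* **Default motif proportions mirror the studied system**: ~92% p1 in
  `hom`, ~91% in `het`, and a 29/32/23% spread over p1/p2/p4 in `wt`, with
  p9 used by no genotype. `noise_sd = 0.04` was chosen so technical pairs
  sit at r ≈ 0.998, comfortably inside the r ≥ 0.98 regime the QC emulates;
  the source data publish no dispersion estimates, so these are synthetic
  defaults, chosen once and documented, not inferred quantities.

What passing recovery tests show — and what they do not: at the defaults the
classifier recovers ≥ 99% of planted motifs, and recovery degrades
monotonically as noise grows. That validates the machinery, not the biology:
real FPKM has heavier tails, correlated genes, batch structure and
mean–variance coupling the generator does not model, so recovery rates here
are upper bounds on real-data behaviour.

`plant_table3_fixture()` is the deterministic end-to-end witness: 8 named
candidate genes carrying their published per-genotype codes (p1 throughout
in `hom`) plus 12 background genes flat everywhere, zero noise, identical
replicates. Classification must reproduce all 60 planted codes exactly and
the unique-extraction must return exactly the 8 names.

## Numerical choices and degenerate inputs

* Half-away-from-zero rounding is implemented directly
  (`round_half_away()`); base R's round-half-even would make 0.305 round to
  0.30 and silently shift boundary calls. A 1e-9 epsilon absorbs binary
  representation error in both rounding and threshold comparison.
* An all-zero gene transforms to (0, 0, 0) and is classified p1 — no
  special-casing.
* Gene identity is case-insensitive after trimming (the panel mixes mouse
  title-case and human upper-case); display forms are preserved everywhere.
* Empty FPKM cells are an error by default; `fill_zero = TRUE` substitutes
  0.0 with a logged message, since the source methodology never describes
  missing-data handling.
* Stage order is configuration (`E14.5 < E15.5 < E16.5`), never a string
  sort.
* The log10(FPKM+1) transform is not scale-equivariant at low expression: a
  global 10× rescale shifts transformed values by exactly 1 only where
  FPKM ≫ 1 (the perturbation is ~0.09 at a transformed value of 0.7 and
  < 0.005 above ~2.2). Direction calls are therefore scale-stable only for
  well-expressed genes with effects away from the rounding boundary, which
  is how the corresponding test is constructed.

## Panel curation

The packaged panel ships 322 genes whose disruption causes cleft palate in
mouse (MGI-derived) or human (OMIM-derived). Per-gene source tags are
assigned by typographic convention (title-case → mouse, upper-case → human)
and flagged heuristic in the provenance, because the transcribed table does
not print a source per gene. `merge_species_lists()` reproduces the curation
logic on user-supplied lists: human symbols pass through a one-to-one
ortholog map (ambiguous maps are rejected, not resolved — whether the
original curation was one-to-one is unknowable from the outside);
post-mapping intersection becomes `common`, unmapped human genes are counted
as non-orthologs and excluded. The merge reports whatever its inputs imply;
it does not force any published total, whose internal accounting
(128 + 230 − 37 vs a stated 322) does not close. Locus-style names without
gene symbols are kept as opaque symbols.

The merge's label symmetry deserves a caveat: swapping the two lists and
inverting the map preserves the common pairs, but *not* the panel size,
because the merge is intentionally asymmetric — unmapped first-list (mouse)
genes are retained while unmapped second-list (human) genes are dropped.

## Reporting

`run_pipeline()` chains QC → classification → differential tabulation → set
comparison → rendering, writing TSV/JSON outputs and a manifest with a
content hash per file. Figures (pheatmap heatmaps with red→yellow ramps and
pattern-block row gaps; schematic Venn circles) are advisory: every figure
has a machine-readable companion table, and all testing runs on the tables.
Within-pattern heatmap rows are ordered alphabetically for determinism, and
empty pattern blocks are skipped.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated data:
the deterministic 20-gene fixture, simulations of 150–1000 genes for
recovery and degradation properties, and a 5000-gene simulation for the
replicate-concordance regime. These sizes were chosen as the smallest at
which the stochastic properties are stable across seeds.

## Known limitations

* No differential-expression statistics: classification is fold-change
  only. The upstream tooling's significance filter is out of scope, so
  differential-set counts here are "FC-significant" and labelled as such.
* Exactly three stages (two transitions); multi-transition motif spaces are
  a non-goal.
* No isoform/splice-variant handling, no read-level simulation, no
  enrichment or network analysis.
* The generator's realism limits are listed above; treat synthetic recovery
  rates as machinery validation, not biological benchmarks.
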