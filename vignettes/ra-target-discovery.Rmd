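---
title: "Finding candidate direct RA target genes from RA-regulated epigenetic marks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding candidate direct RA target genes from RA-regulated epigenetic marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(raretarget)
```

## The problem

Retinoic acid (RA) signals through RAR/RXR heterodimers bound to RA
response elements (RAREs). Removing RA synthesis from an embryo changes
the expression of thousands of genes, but most of those changes are
indirect. The pipeline implemented here narrows that list to genes that
are plausibly *direct* transcriptional targets by requiring three
independent lines of evidence to coincide:

1. **Differential expression** of the gene in the knockout (KO) versus
   wild type (WT).
2. A **differential histone-mark peak** (H3K27ac, an activation mark, or
   H3K27me3, a repression mark) linked to the gene — either as the gene
   with the nearest annotated promoter, or as a differentially expressed
   gene sharing the peak's topologically associating domain (TAD).
3. A **RARE motif inside the linked peak**, classified as a candidate
   enhancer or silencer and tiered by cross-species conservation.

The coincidence requirement is the point: each criterion alone has a high
false-positive rate (thousands of differentially expressed genes, roughly
14,000 potential RAREs in a vertebrate genome), but a gene whose
expression change, local chromatin change, and motif evidence all agree is
a strong candidate for knockout follow-up.

## Conventions and the core model

All internal coordinates are 0-based half-open (BED convention); region
strings such as `chr6:52153426-52153442` are 1-based inclusive (UCSC
style) and converted on parse/format, with en-dashes and thousands commas
tolerated on input. The midpoint of an even-length interval is the lower
of the two central positions — a deterministic tie-break that matters
because peak-to-gene distances are anchored on peak midpoints.

### Differential filters

Expression: a gene is **RA-activated** when its log2FC (KO vs WT) is
strictly below −0.85 and **RA-repressed** when strictly above +0.85, with
FPKM strictly above 0.5 in *both* conditions. The 0.85 cutoff is the
published calibration chosen so that the known RA target *Sox2*
(log2FC −0.86) is included; the FPKM floor removes genes too weakly
expressed for a reliable fold change. All comparisons are strict, so a
gene at exactly ±0.85 is excluded.

Peaks: |log2FC| strictly above 0.51 (H3K27ac) or 0.47 (H3K27me3), with a
Benjamini–Hochberg adjusted p-value below 0.05. The two mark-specific
cutoffs are likewise published calibrations (to include a known
RA-regulated peak near *Sox2* and *Fst* respectively). BH adjustment is
applied **per mark** — the two marks are separate experiments — and is
computed by the package's own step-up implementation when the input table
carries only raw p-values; an existing `bh_p` column is trusted as
externally adjusted. An optional BH filter on expression p-values exists
(`rna_bh_alpha`) but is disabled by default, since the effect-size/FPKM
cutoffs are the primary published filter.

### Peak-to-gene linking

Each significant peak links to the gene minimising
|peak midpoint − TSS|, ties broken lexicographically by gene id so the
result is order-independent. The midpoint anchor follows the convention of
the standard peak-annotation tooling; an `edge` anchor (distance to the
nearer peak boundary, 0 if the TSS is inside the peak) is available as a
configuration option. Secondarily, every *differentially expressed* gene
whose TSS lies in the same TAD as the peak midpoint is linked as a
`tad`-type link, excluding the gene already linked as nearest. Membership
is by **TSS containment**, not gene-body overlap, so a gene spanning a TAD
boundary is assigned to exactly one TAD; a peak spanning a boundary
belongs to the single TAD containing its midpoint. Peaks outside any TAD,
or runs without a TAD table, degrade to nearest-only linking (logged).

### The RARE scanner

The published analyses report RAREs as consensus sequences with mismatch
counts, not position-weight matrices, so the scanner implements exactly
that representation: a RARE is two 6-bp half-sites matching the IUPAC
consensus `RGKTCA` (R = A/G, K = G/T) separated by a 1, 2, or 5 bp spacer
(DR1/DR2/DR5), scanned at every offset on both strands. Mismatches are
counted over the 12 half-site positions only — the spacer is
unconstrained, which is consistent with the printed perfect-consensus
elements whose spacers vary freely. `N` never matches; windows running off
the sequence end are skipped. The default tolerance is 2 mismatches for
discovery scans and 1 for the highly conserved tier.

`RGKTCA` rather than the literal `AGGTCA` is deliberate: the printed
perfect half-sites include `GGGTCA`, `AGTTCA`, and `GGTTCA`, i.e. A/G at
position 1 and G/T at position 3 are consensus-conforming. The consensus
is configurable for stricter or looser definitions.

Overlapping matches of different types (a DR1 nested in a DR5 window, the
same window on both strands) are all reported; downstream consumers see
every typed element, mirroring tables that list "DR5, DR1" for a single
peak.

### Classification and integration

Element class is determined **solely by the gene's expression
direction**: RAREs attached to RA-activated genes are candidate
*enhancers*, to RA-repressed genes candidate *silencers*. The mark
direction is recorded as a boolean concordance flag rather than used as a
veto, because a silencer can legitimately sit inside an H3K27ac-gain
peak. A RARE is attached to a linked peak when it overlaps by at least
1 bp (elements at peak edges are real in practice); a strict
fully-contained mode is available. A RARE linked to genes of opposite
directions receives both classifications, one per target row, with a
warning — the data cannot distinguish which gene the element serves.

### Conservation tiers

Published conservation calls came from manual genome-browser homology
inspection, which is not reproducible programmatically. The package
operationalises "conserved in clade c" as: *the supplied orthologous
window for c contains a same-type DR match within 1 mismatch, on either
strand*. Windows are an explicit per-clade FASTA input keyed by RARE
identifier; alignment gaps are stripped before scanning. The tier is the
most distal conserved clade in the order rodent < human < bird < reptile
< frog < fish, and a distal match sets the tier even when intermediate
clades are missing (tiers, not paths, are reported). The **highly
conserved** filter keeps RAREs with tier beyond mammals (bird or more
distal) and at most 1 mismatch, then collects the distinct genes (nearest
plus same-TAD) they point to.

The packaged fixture of 24 highly conserved RAREs reproduces its published
tallies exactly:

```{r}
check_conserved_rare_table()
```

## The synthetic-data generator

`simulate_ra_inputs()` exists so that every stage is testable without any
download. It emulates the statistical structure the analysis assumes:

- background sequence i.i.d. uniform ACGT; genes placed non-overlapping
  (one per equal-width slot); TADs tile each chromosome contiguously with
  breakpoints on a 20 kb grid;
- each true target gets one peak whose midpoint lies within 10 kb of the
  TSS — or, for a configurable fraction (default 0.2), elsewhere in the
  gene's TAD, exercising the TAD-rescue path — with the peak constrained
  to the gene's TAD so the planted link is recoverable;
- a RARE of sampled type (DR1/DR2/DR5) and mismatch count (0 or 1) is
  planted *by substitution* inside the peak, so coordinates stay stable;
- true log2FCs are sign-correct (per the concordance table) with
  magnitude ~ |Normal(2.0, 0.3)| truncated above the relevant threshold;
  true raw p-values ~ Uniform(0, 1e-4); true FPKMs floored above the
  expression filter. The 2.0 effect mean sits inside the observed range of
  the real study's worked examples (mark |log2FC| up to ~1.2, RNA
  |log2FC| up to ~5.4);
- null genes and peaks have log2FC ~ Normal(0, 0.2) and p ~ Uniform(0,1),
  so nulls are rejected jointly by the effect-size threshold and the BH
  cut;
- ortholog windows are the mouse RARE ±30 bp copied for clades up to the
  planted tier and random sequence beyond, rejection-sampled so a
  non-conserved window never contains a same-type match within tolerance —
  making the planted tier exactly recoverable;
- everything is reproducible from the seed.

What the generator does **not** model: repeat structure or GC skew in the
background (the scanner is consensus-based, so composition affects only
false-positive rates, which the oracle tests cover), read-level noise
(p-values are generated, not computed from counts — the differential test
itself is upstream of this package), peak-shape, and real orthology
(windows are planted, not aligned). Passing recovery tests therefore
demonstrate the pipeline's correctness as a deterministic integration of
its inputs, not the upstream callers' sensitivity on real data.

```{r}
sim <- simulate_ra_inputs(simulation_params(seed = 42))
run <- run_ra_pipeline(sim$expr, sim$peaks_k27ac, sim$peaks_k27me3,
                       sim$genome, sim$genes, sim$tads,
                       sim$ortholog_windows, quiet = TRUE)
glance(run)
rep <- recovery_report(run, sim$truth)
c(precision = rep$gene_precision, recall = rep$gene_recall,
  rare_recovery = rep$rare_recovery)
```

```{r, fig.width = 6, fig.height = 3.5}
plot_conservation_tiers(run$candidates)
```

## Numerical and design choices

- **Strict thresholds.** All cutoff comparisons use strict inequalities,
  matching the published "log2 < −0.85 or > 0.85" notation; boundary ties
  are excluded.
- **BH step-up.** `bh_adjust()` is the textbook step-up
  (`min over ranks j >= rank(i) of p_(j) * n / j`, capped at 1), verified
  against an independent brute-force oracle and `stats::p.adjust` to
  1e-12 in the test suite.
- **Tie-breaks.** Nearest-gene ties go to the lexicographically smaller
  gene id; even-length midpoints take the lower central position; output
  tables are sorted by (chrom, start, gene, RARE) so identical inputs give
  byte-identical files.
- **Degenerate inputs.** Empty peak tables, chromosomes without genes,
  peaks outside every TAD, gap-only conservation windows, and empty
  candidate sets all produce well-defined (empty or flagged) results
  rather than errors; malformed files fail hard with line numbers.
- **Problem sizes.** The test suite runs the scanner/brute-force
  equivalence on 10,000 random sequences of lengths 13–40 at tolerances
  0–2, the BH oracle on 1,000 random vectors, and five full synthetic
  runs at 50 true targets / 500 null genes / 200 null peaks on 4 Mb of
  genome — sizes chosen so the whole suite completes in a couple of
  minutes while still exercising every code path at genome-like density.

## Limitations

- The scanner is consensus/mismatch based by design; it will not reproduce
  the ranked scores of a PWM scanner, only presence/absence within a
  mismatch budget.
- Conservation requires precomputed orthologous windows; the package does
  not compute whole-genome alignments or liftovers.
- DR0/DR3/DR4 spacers, GTF gene models, and BAM/bigWig ingestion are out
  of scope; the differential count test itself (e.g. a DESeq2 analysis)
  must be run upstream, with its log2FCs and p-values supplied as input.
- Gene identity is by case-sensitive symbol string; no alias resolution is
  attempted.
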