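---
title: "Loop-aware assignment of nuclear-receptor binding sites to hormone-responsive genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop-aware assignment of nuclear-receptor binding sites to hormone-responsive genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopweaver)
```

## The problem

Estrogen and progesterone receptors (ESR1, PGR) bind chromatin both at gene
promoters and at distal enhancers, often hundreds of kilobases from the genes
they regulate. The common shortcut — assign each ChIP-seq peak to the nearest
gene within some cap, typically 100 kb — ignores the three-dimensional folding
of chromatin that brings distal enhancers into contact with promoters.
`loopweaver` implements the alternative: use Hi-C chromatin loops to enumerate
the geometrically plausible peak–gene contacts, intersect them with
differential expression, and quantify what the loop-aware assignment adds over
the closest-gene baseline.

The package is written for analysts who already have peak calls (BED), loop
calls (BEDPE), gene models (BED12/GTF), a compartment eigenvector (bedGraph),
and an RPKM matrix with a treatment design, and who want a deterministic,
testable pipeline from those files to per-category gene tallies.

## Loop anatomy and the four interaction categories

A loop is a pair of anchor intervals on one chromosome; the *span* is the
region between the end of the left anchor and the start of the right one,
`[left_end, right_start)`. Relative to a loop, a peak can meet a gene four
ways:

* **direct** — the peak overlaps the gene's promoter window,
  `[TSS - h, TSS + h)`. No loop is involved. The half-width `h` defaults to
  2,500 bp; "promoter" has no universal numeric definition, so `h` is an
  explicit parameter rather than a constant.
* **anchor/anchor** — the peak overlaps one anchor and the gene's TSS lies in
  the *opposite* anchor: the loop juxtaposes enhancer and promoter.
* **anchor/span** — the peak overlaps an anchor and the gene's TSS lies
  strictly inside the span.
* **span/anchor** — the peak lies in the span (and in neither anchor) and the
  gene's TSS lies in either anchor.

Membership rules are deliberately asymmetric: a *peak* belongs to a loop part
by any-overlap (at least 1 bp), while a *gene* belongs by TSS containment —
genes are "in" a loop end when their transcription start site falls inside
it. A peak straddling an anchor/span boundary counts as anchor, never as
span, so one peak cannot be double-counted against the same loop. A peak and
a TSS sharing one anchor yield no anchor/anchor record (such pairs are close
enough that the loop adds nothing); they are reported in a diagnostic side
table instead. Where the span/anchor rule does not specify which anchor must
hold the TSS, either anchor qualifies.

`classify_interactions()` emits every qualifying (peak, gene, category, loop)
tuple exactly once. A pair may legitimately hold several categories across
loops — a gene can sit at a promoter peak, on the far anchor of one loop and
inside the span of another — and the per-category tallies deduplicate genes
within categories while the cross-category union counts each gene once.

## Differential expression rules

The expression stage reproduces a specific, fully explicit preprocessing
recipe on RPKM values:

1. **Low-expression filter.** Compute MAX, each gene's maximum RPKM over all
   samples; drop genes with MAX strictly below 1% of the mean of the entire
   matrix (a dataset with mean RPKM 2.0 gets cutoff 0.02). The threshold is
   attached to the filtered matrix and reused on re-application, so filtering
   is idempotent by construction — recomputing it on already-filtered values
   would quietly raise the bar on each pass.
2. **Zero replacement.** Vehicle-group zeros become `0.0005 * MAX(gene)`
   (0.05% of MAX), making treatment/vehicle ratios finite. Zeros in treated
   groups are left alone: they only ever shrink a fold change's numerator.
3. **Testing.** Fold change is the ratio of arithmetic group means of the
   zero-replaced RPKM. Inference runs on `log2(RPKM + 1e-3)`: a one-way ANOVA
   across all design groups supplies the pooled within-group mean square, and
   each contrast is the pooled-variance t-test on `N - k` degrees of freedom.
   With n = 3 per group a Welch test would retain as few as 2 df and cannot
   reach useful power at realistic noise (σ = 0.25 on log2); pooling across
   groups is both the classical ANOVA contrast and what commercial ANOVA
   tools compute. `method = "welch"` remains available for heteroskedastic
   designs. P-values are Benjamini–Hochberg adjusted per contrast.
4. **DEG gate.** A gene is differentially expressed when the fold change is
   at least 2 (either direction) *and* the adjusted p is below 0.05 — both
   conditions, jointly.

Donors are analyzed separately, each against its own vehicle control, and
`union_deg()` pools the per-donor calls, carrying each donor's fold change.
Outlier samples are removed only via the explicit `exclude_samples` argument;
the package does not re-derive outlier calls automatically because no
reproducible criterion exists for them.

## Peak location annotation

`annotate_peak_location()` classifies each peak by its midpoint against gene
models, in priority order 5' UTR > exon > 3' UTR > intron for any gene body
containing the point ("exon" means exonic bases outside both UTRs, so every
base in a gene body has exactly one class and the categories partition the
peaks). Points outside all gene bodies are binned strand-aware by distance to
the nearest gene: upstream/downstream within (0, 5 kb] and (5 kb, 25 kb], and
distal beyond 25 kb. Only the 25 kb outer boundary has a published anchor
("> 25 kb" distal); the 5 kb inner edge follows the annotation tool
convention this scheme emulates and is documented as an assumption. Ties are
always broken toward the higher-priority feature and then the smaller gene
id, which makes the output order-invariant.

## Compartments

A/B compartments come from the sign of a Hi-C eigenvector at 100-kb
resolution. Because an eigenvector's sign is arbitrary per chromosome,
`label_compartments()` defaults to orienting by gene density: per chromosome,
the sign is flipped when positive-value bins are less TSS-dense than
negative ones, enforcing "A = gene-dense = active". `as_is` trusts the input
sign (used for simulated tracks, which are emitted pre-oriented). Bins with
eigenvalue exactly 0 are unlabeled rather than forced to a side. Peaks map to
the bin containing their midpoint, so each peak counts once, and the B
fraction is reported over A+B-assigned peaks.

## The synthetic landscape generator

`landscape_spec()` + `generate_landscape()` build toy genomes whose ground
truth is exact by construction, not by re-running the classifier:

* Loops are placed non-overlapping and non-nested, and every planted
  loop-mediated tuple gets a dedicated loop containing exactly one planted
  peak and one partner gene in the stipulated geometry. Exclusion zones
  (peaks at least 2 kb inside their anchor, genes confined to their anchor,
  background elements at least 3 kb from loops and 6 kb from each other,
  nothing but direct peaks near promoters) guarantee the classifier recovers
  exactly the planted tuples and nothing else. Overlapping/nested loops and
  arbitrary placements are exercised separately by randomized
  oracle-equivalence tests.
* Compartment labels are planted at bin level. Peaks sharing a 100-kb bin
  must share a label, so hitting a target B fraction is a subset-sum over
  occupied-bin peak counts; the generator solves it exactly by dynamic
  programming, relocating unassigned peaks into fresh bins when no integral
  solution exists, and records the achieved fraction in the ground truth.
* Expression is lognormal per gene: baseline log2 means ~ N(3, 1.5),
  replicate noise σ = 0.25 on log2, a treatment group multiplying planted
  up-genes by fold 4 (down-genes by 1/4), and a co-treatment group applying
  `fold^a` with attenuation exponent `a = 0.5` — reproducing the attenuated
  induction pattern of a progestin added on top of estrogen (`a = 1` makes
  the two treatment groups identical, `a = 0` collapses the third group to
  baseline). A small fraction (2%) of baseline values in unplanted genes is
  zeroed to exercise the zero-replacement rule.

Default sizes — 6 chromosomes of 10 Mb, 100 loops of 30–250 kb extent with
5–15 kb anchors, 160 genes, 300 peaks with 30/20/25/40 planted
direct/anchor-anchor/anchor-span/span-anchor and the rest unassigned, 68% of
peaks in B, 3 replicates per group — were chosen once to mirror the structure
of a two-donor hormone-treated organoid study at a scale where every test
recomputes from scratch in seconds. What the generator does *not* emulate:
read-level noise, peak-call uncertainty, overlapping transcription units at
planted sites, nested loop hierarchies at planted sites, and donor-specific
library quality. Passing closure tests therefore demonstrate the *logic* is
exact, not that real data meet the generator's assumptions.

All generator randomness flows from a single integer seed; identical spec and
seed give byte-identical output files.

## Numerical and degenerate-input choices

* All interval logic is 0-based half-open; GTF is converted at the I/O
  boundary, eliminating off-by-one ambiguity. Chromosome names match as exact
  strings, with an optional `chr`-prefix normalization flag.
* Multi-transcript genes collapse to the longest transcript (tie: smallest
  transcript id) because every downstream rule is per-gene.
* "Within 100 kb" is inclusive (`<= 100000`); distances to genes are
  minimum gaps to TSS or TES, 0 when the peak contains either point.
* Zero-width spans (adjacent anchors) are legal and flagged; inter-
  chromosomal BEDPE records are dropped with a reported count; anchors are
  reordered left-first and records whose anchors overlap are rejected with a
  warning.
* Zero within-group variance in the contrast test resolves by the mean
  difference alone (p of 0 or 1), instead of propagating NaN.
* Peak-set overlap (`overlap_peak_sets()`) counts a pair at >= 1 bp
  intersection by default (configurable), reports fractions over both
  original sets, and merges shared clusters to maximal union intervals.

## Reporting

`run_pipeline()` chains the stages, echoes every parameter actually used in
its report, writes deterministic TSV/JSON outputs, and records MD5 checksums
so reruns can be compared byte for byte. Stage errors abort with the failing
stage named. A worked end-to-end example with the numbers it prints is in the
README; `scripts/acceptance.R` re-derives the headline quantities (oracle
agreement, planted-truth recovery, compartment fraction, capture comparison,
Monte-Carlo error rates) from scratch.

```{r example}
report <- run_pipeline(list(simulate = TRUE, seed = 1, landscape = list(
  n_chromosomes = 2, n_loops = 14, n_peaks = 50, n_genes = 40,
  category_mix = c(direct = 5, anchor_anchor = 4, anchor_span = 4,
                   span_anchor = 4),
  deg_spec = list(n_up = 8, n_down = 4))))
report
```

## Known limitations

* The loop-mediated categories are geometric candidates, not validated
  regulatory interactions; no contact-frequency weighting or significance
  testing of peak–loop enrichment is attempted.
* The closest-gene baseline assigns one gene per peak; genes equidistant from
  a peak resolve deterministically (smaller id) rather than probabilistically.
* Shared-loop detection is all-pairs within chromosomes and intended for
  loop sets in the thousands, not millions.
* The DEG stage models lognormal noise with a common within-group variance
  per gene; count-based models (negative binomial) are out of scope because
  the input unit is RPKM, not raw counts.
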