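# loopweaver

Chromatin-loop-aware assignment of nuclear-receptor ChIP-seq peaks to
hormone-responsive genes.

## What it does

Estrogen and progesterone receptors (ESR1, PGR) bind distal enhancers as well
as promoters. The usual shortcut — assign each peak to the closest gene
within 100 kb — misses enhancers that act through chromatin loops.
`loopweaver` integrates four data layers:

* ChIP peak calls (BED / narrowPeak),
* Hi-C chromatin loops (BEDPE),
* gene models (BED12 or GTF),
* a 100-kb A/B compartment eigenvector (bedGraph) and an RPKM expression
  matrix with a treatment design (TSV),

and classifies every peak–gene relation against loop anatomy. With a loop
split into left/right **anchors** and the **span** between them, a peak can
meet a gene four ways:

| category | peak | gene TSS |
|---|---|---|
| `direct` | overlaps `[TSS − h, TSS + h)`, default h = 2.5 kb | — |
| `anchor_anchor` | in one anchor | in the opposite anchor |
| `anchor_span` | in an anchor | strictly inside the span |
| `span_anchor` | in the span (not in an anchor) | in either anchor |

Peaks belong to loop parts by any-overlap; genes by TSS containment. Each
qualifying (peak, gene, category, loop) tuple is emitted once.

Differential expression follows an explicit RPKM recipe: genes with
MAX (per-gene maximum RPKM) below 1% of the dataset-mean RPKM are filtered;
vehicle-group zeros become 0.05% of MAX; fold change is the ratio of group
means; testing is a one-way ANOVA on log2(RPKM + 1e-3) with pooled-variance
contrasts, BH-adjusted; a DEG needs |fold| ≥ 2 **and** FDR p < 0.05. Donors
are analyzed separately and unioned. The loop-aware DEG assignment is then
compared against the closest-gene-within-100-kb baseline, and peak sets are
co-localized with A/B compartments (peak midpoint → 100-kb bin → eigenvector
sign, oriented by gene density).

A synthetic-landscape generator (`landscape_spec()`,
`generate_landscape()`, `simulate_expression()`) builds toy genomes with
machine-readable planted ground truth — peak categories, DEG status,
compartment labels — so the entire pipeline is testable end to end without
external data.

## Worked example

```r
library(loopweaver)
report <- run_pipeline(list(simulate = TRUE, seed = 1))
report
#> pipeline_report
#>   DEG (E2 vs V): 60
#>   per-category expressed / DEG / captured-by-closest:
#>     direct            30 /   11 /   11
#>     anchor_anchor     20 /    7 /    1
#>     anchor_span       25 /    9 /    7
#>     span_anchor       40 /   14 /   10
#>   peaks in B compartment: 0.680
```

Reading the table: of the 30 expressed genes with a direct promoter peak, 11
are estrogen-responsive DEG, and all 11 are also found by the closest-gene
baseline — direct assignments never need the loops. In the three
loop-mediated categories the baseline recovers only a subset (1/7, 7/9,
10/14 here): the genes it misses sit beyond 100 kb of every peak and are
reachable only through the loops. Across categories the DEG union is 41
genes, of which the baseline captures 29 — the loop-aware analysis finds the
remaining 12. The 68% B-compartment fraction is the generator's planted
value, recovered exactly.

The same stages run on real files:

```r
report <- run_pipeline(list(
  peaks = "esr1_peaks.bed", loops = "shared_loops.bedpe",
  genes = "genes.bed12", eigenvector = "eigenvector.bedgraph",
  expression = "rpkm.tsv", design = "design.tsv",
  baseline_group = "V", contrast = c("E2", "V"),
  promoter_halfwidth = 2500, max_distance = 100000,
  outdir = "results/"))
```

or individually: `read_bed()`, `read_bedpe()`, `read_gene_models()`,
`filter_low_expression()`, `replace_vehicle_zeros()`, `call_deg()`,
`union_deg()`, `derive_loop_parts()`, `shared_loops()`,
`classify_interactions()`, `integrate_with_deg()`, `closest_gene_within()`,
`compare_with_closest_gene()`, `annotate_peak_location()`,
`label_compartments()`, `peaks_in_compartments()`. A thin command-line
front-end lives at `inst/exec/loopweaver.R`
(`loopweaver.R run|simulate|integrate|annotate|overlap|closest|compartments`).

See `vignettes/loop-aware-integration.Rmd` for the full model description,
parameter semantics, and design rationale.

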