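# regulomer

Consensus regulome integration and cell-cycle phenotyping for studies of
transcription-factor competition.

## The problem

A fusion oncoprotein that keeps the DNA-binding domain of its native
counterpart — the situation for ETV6-RUNX1, which carries the RUNX1 Runt
domain — competes with the native factor for the same binding sites and
target genes. Characterising that competition means stitching together
several assay layers:

* **High-confidence binding sites.** Replicate ChIP-seq peak sets are
  merged and filtered for support by independent antibodies/samples and by
  open chromatin (DNaseI hypersensitivity), then annotated to nearest
  genes with strand-aware signed summit-to-TSS distances.
* **Binding × expression.** Per-gene binding flags are tested for
  overrepresentation across expression-ranked bins (or up/dn/ns groups)
  with one-sided Fisher tests, BH-adjusted across bins:
  for bin *b*, a 2×2 table of (bound, unbound) × (in *b*, outside *b*).
* **Site ownership.** Where both factors are profiled in the same cells,
  peaks are classified by the pseudocounted CPM log-ratio
  *r* = log₂((CPM_fusion + c)/(CPM_native + c)) into R1 (*r* ≤ −τ), ER
  (*r* ≥ τ), or shared R1_ER, and chromatin consequences are summarised as
  class proportions over 11 bins of peaks ranked by
  sign(LFC)·−log₁₀(p) of differential H3K27ac.
* **Core programs.** Across ≥2 knockdown cell lines, core targets satisfy
  padj < 0.1 with a consistent fold-change direction in every pairwise
  comparison plus joint LRT padj < 0.05; preranked GSEA (running-sum ES,
  gene-label permutation null) summarises signatures.
* **Meta-scores.** Per-gene cell-cycle study counts and signed p53 scores
  are binned and summarised as mean log-fold-change ± 90% t-intervals,
  with Welch t-tests between the p53 score ≤ −17 (cell cycle), ≥ 17
  (apoptosis/DNA damage) and control groups.
* **Mass-cytometry phenotype.** Events are arcsinh-transformed, clustered
  with a batch self-organizing map, merged into metaclusters and labelled
  by an ordered marker-threshold rule table (dead → apoptotic → M → S →
  G2 → G1 → G0); condition × phase tables are tested by Pearson
  chi-squared with adjusted standardized residuals (6 categories ⇒ df = 5).

A synthetic-data module generates every input with planted ground truth —
shared true binding sites with per-set noise, DE tables with planted
binding→repression coupling, CPM pairs with planted classes, meta-score
tables with planted trends, CyTOF events with planted populations and
phase mixtures — so the whole chain is testable end to end with no
external downloads.

## Worked example

The pipeline driver runs the full chain on synthetic data and writes every
stage output plus a JSON report:

```r
library(regulomer)
cfg <- run_config(seed = 1, outdir = "demo_run")
report <- run_pipeline(cfg)

str(report$stages$consensus)
#> List of 4
#>  $ n_merged            : int 1419
#>  $ n_consensus         : int 950
#>  $ recall_true_sites   : num 0.972
#>  $ false_discovery_rate: num 0

head(read_tsv("demo_run/enrichment_bins.tsv")[,
     c("bin_label", "n_genes", "n_bound", "odds_ratio", "pvalue", "padj")], 3)
#>   bin_label n_genes n_bound odds_ratio   pvalue     padj
#> 1    bin_01     150      96       2.12 1.33e-05 0.000133
#> 2    bin_02     150      88       1.65 2.48e-03 0.012382
#> 3    bin_03     150      82       1.38 3.80e-02 0.126645

str(report$stages$cytof)
#> List of 5
#>  $ phase_accuracy     : num 0.975
#>  $ population_accuracy: num 0.993
#>  $ chisq_statistic    : num 354
#>  $ chisq_df           : int 5
#>  ...
```

Reading the numbers: of 1419 merged ChIP peaks, 950 survive the
two-antibody + open-chromatin support filter, recovering 97.2% of the
planted true sites with no false consensus peaks. The planted repressive
coupling (bound genes shifted down by 0.5 noise-sd) concentrates bound
genes in the most down-regulated expression bins — bin 1 holds 96 bound
genes of 150 (odds ratio 2.1, BH-adjusted p = 1.3e-4) and significance
decays by bin 3 — while the CyTOF stage recovers planted cell-cycle phases
at 97.5% event-level accuracy and detects the planted S-phase excess
(chi-squared = 354, df = 5, fusion-condition residual maximal at S).

Every analysis step is also exposed directly (`merge_intervals()`,
`support_filter()`, `nearest_gene()`, `fisher_2x2()`,
`binned_binding_enrichment()`, `classify_peaks()`,
`core_consensus_filter()`, `gsea_preranked()`, `bin_by_score()`,
`train_som()`, `metacluster_annotate()`, `phase_distribution_test()`, …);
see the methods vignette (`vignettes/regulome-integration-methods.Rmd`)
for the models, defaults and design decisions.

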