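---
title: "Methods: consensus regulome integration and cell-cycle phenotyping"
author: "regulomer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus regulome integration and cell-cycle phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulomer)
```

# The scientific problem

A chimeric transcription factor that retains the DNA-binding domain of its
native counterpart — the situation for the ETV6-RUNX1 fusion of childhood
B-cell precursor leukemia, which carries the RUNX1 Runt domain — competes
with the native factor for the same binding sites and the same target
genes. Characterising that competition requires integrating several assay
layers:

1. **Where does the factor bind?** Replicate ChIP-seq peak sets (multiple
   antibodies, multiple samples) are intersected with each other and with
   open chromatin (DNaseI hypersensitivity) to define high-confidence
   binding sites, which are then annotated to their nearest genes.
2. **What happens to bound genes?** Binding flags are crossed with
   differential-expression tables, either across expression-ranked bins or
   across up/down/not-significant groups, with one-sided Fisher tests and
   Benjamini–Hochberg control.
3. **Which sites belong to whom?** Where both factors are profiled in the
   same cells, per-peak CPM signal ratios classify sites as
   native-dominated (R1), fusion-dominated (ER), or shared (R1_ER), and
   chromatin consequences (H3K27ac loss) are read out across ranked bins of
   differential acetylation.
4. **What is the conserved program?** Knockdown experiments across several
   cell lines define a core target set (consistent pairwise significance
   and direction, plus a joint LRT), summarised further by preranked GSEA.
5. **What does the phenotype look like?** Mass cytometry with cell-cycle
   markers (pRb, IdU, cyclin B1, phospho-histone H3) and viability markers
   (cisplatin, cleaved caspase-3) quantifies the distribution of cells over
   cell-cycle phases per population and condition.

The package implements each layer as a small set of composable functions,
plus a synthetic-data module that generates all inputs with planted ground
truth so that the full chain is testable without any external data.

# Interval layer

Coordinates are 0-based half-open throughout (BED convention); narrowPeak
summits are offsets from the interval start, with −1 meaning absent and a
midpoint fallback (`floor((start+end)/2)`). Overlap means at least one
shared base; `support_filter()` optionally requires a minimum overlap
fraction of the reference peak.

`nearest_gene()` anchors annotation at the peak summit (the package's
analyses are summit-centric — motif windows and signal heatmaps are all
summit-centered), and signs distances so that negative means 5′ of the TSS
on the gene's strand. Ties are broken by smaller distance, then
lexicographic gene id, making annotation deterministic. The category rule
is applied in a fixed order: promoter (`|d| <= 1` kb), intragenic (summit
inside the gene body), upstream proximal (1–10 kb upstream), upstream
distal (> 10 kb upstream), downstream. The 1 kb and 10 kb boundaries and
the 100 kb association radius are configurable; published figures rarely
print their exact bin edges, so these defaults are package conventions, and
a summit within 1 kb of a TSS is always called `tss` even when other rules
would also match.

# Statistical kernel

* `fisher_2x2()` computes the conditional hypergeometric test directly from
  `dhyper`. "One-way" enrichment tests are `alternative = "greater"`. The
  reported odds ratio is the unconditional sample estimate `ad/bc` (the
  conditional MLE differs; only p-values feed downstream decisions).
* `bh_adjust()` validates inputs and applies Benjamini–Hochberg step-up
  adjustment; adjustment is always across the bins of one analysis.
* Bin backgrounds are *all genes outside the bin*, not a genome-wide
  constant, matching the "compared with all other genes" framing of
  enrichment bar plots.
* The up/dn groups use `padj < 0.05` with the fold-change sign; the ns
  group uses raw `p > 0.05`. These thresholds follow common figure-legend
  conventions and are configurable. The three groups deliberately do not
  partition the gene universe (genes with `padj >= 0.05` but `p <= 0.05`
  belong to neither).
* `chisq_homogeneity()` reports the Pearson statistic with
  `df = (R-1)(K-1)` — six phase categories against two conditions give
  df = 5, five populations give df = 4 — and *adjusted* standardized
  residuals `(O-E)/sqrt(E(1-rowfrac)(1-colfrac))`, the conventional
  "standardized residuals" of mainstream statistical software.

# Peak classification

CPM is the only normalization applied to per-peak counts (no TMM-style
composition correction; peak-level comparisons between libraries of similar
composition do not need it, and the classification is a ratio so
library-size effects cancel to first order). The three-way call uses the
pseudocounted log ratio `r = log2((cpm_fusion + c)/(cpm_native + c))` with
defaults `tau = 1` (2-fold) and `c = 0.5`. Published analyses do not print
their cutoff; `classify_tau_sweep()` exposes the sensitivity of the class
composition to `tau`, and exported tables embed the parameters as header
comments. A statistical test per peak (as DiffBind would produce) is a
deliberate non-goal: differential-binding p-values are consumed as an input
table when available, not refitted.

Ranked-bin analyses sort peaks by `sign(log2fc) * -log10(p)` of the
differential-acetylation test, split them into `k = 11` equal bins (ties
broken by peak id) and report per-bin class proportions.

# Core programs and GSEA

The core filter is exactly the published rule: `padj < 0.1` with the same
fold-change direction in every pairwise (knockdown vs control) comparison
across the five cell lines, and joint LRT `padj < 0.05`. Both cutoffs are
arguments. The rank metric for LRT-derived tables is
`sign(LFC) * -log10(p)`; Wald-derived tables can rank by the statistic
column directly. Zero p-values are clamped to the smallest positive double
rather than dropped.

`gsea_preranked()` implements the classic running-sum score: hits weighted
by `|score|^w` (normalized to sum 1), misses by `1/(N-k)`, ES the extremum
of the running sum. The default `w = 1` is the classic "weighted"
statistic, the convention of standard GSEA implementations run with default
arguments; `w = 0` gives the Kolmogorov–Smirnov-like unweighted score.
Because only preranked lists exist at this stage, the null permutes gene
labels (equivalently, hit positions), not phenotypes. The p-value is the
fraction of same-sign null ES at least as extreme — it can be exactly 0 at
finite permutation counts — and NES divides ES by the mean |ES| of the
same-sign null. The leading edge is the set members at or before the
extremum (at or after, for negative ES).

# Meta-score integration

Genes carry two meta-analysis scores: the number of independent studies
calling the gene a cell-cycle gene (0–12), and a signed p53 score where
strongly negative values mark p53-repressed cell-cycle genes and strongly
positive values p53-induced apoptosis/DNA-damage genes. Binning is
half-open `[e_i, e_{i+1})` with explicit edges (the p53 default width is 5;
published figures do not print their width). Per-bin fold-change summaries
use mean ± t-based 90% confidence intervals. The ±17 grouping reproduces
the published three-group rule; group contrasts use two-sided *Welch*
unpaired t-tests ("two-way, unpaired t-test" in figure-legend language) —
Welch because the outer groups are smaller and more variable than the
control bulk — with the usual star bands down to p < 0.0001.

# Mass-cytometry phase assignment

Preprocessing is the CyTOF standard: `asinh(x/5)` (the cofactor is
configurable) followed by per-marker scaling of the 1st–99th percentile
range to [0, 1]. Events are assumed to be upstream-gated viable CD45+
singlets; debarcoding, bead normalization and spillover are out of scope.

Clustering is a batch self-organizing map: per epoch, events map to their
nearest codebook vector and every codebook is replaced by the
neighborhood-weighted mean of all events, with a Gaussian neighborhood
whose σ decays linearly from half the grid radius to effectively zero, so
the final epochs perform near-hard local averaging and the map converges
to within-node means (a 1×2 grid on two well-separated blobs recovers the
blob means; a 1×1 grid recovers the data mean). Batch updates make the
result independent of event order, and seeded initialisation makes it
reproducible. Phase maps are trained on the cycle + viability markers
only, population maps on the surface markers only — mixing the two marker
classes would cluster by population first and phases would never separate.

Annotation replaces the manual cluster labelling of interactive analyses
with an explicit, ordered first-match rule table applied to metacluster
medians: dead (cisplatin high) → apoptotic (cleaved caspase-3 high) → M
(pHisH3 high) → S (IdU high) → G2 (CycB1 high) → G1 (pRb high) → else G0;
populations analogously via CD19/CD34/CD45RA with an intermediate ("mid")
band for the CD19-low precursor population. "High" means the median
exceeds a per-marker threshold set at the midpoint of the two component
means of a one-dimensional two-component Gaussian mixture over all events
(equal-variance components — an unequal-variance fit can split the skewed
dominant mode of a rare-positive marker such as pHisH3 and put the
threshold inside the negative mode; the marker median is the fallback when
the fitted means are closer than 0.1 scaled units). The metacluster count
defaults to `k = 10`, deliberately larger than the seven phase/viability
labels: several metaclusters may share a label, whereas cutting the
average-linkage tree at exactly the number of expected labels can force
two genuine categories (G0 and G1, which differ only in pRb) into one
metacluster. Over-cluster-then-annotate is the standard practice of
SOM-based cytometry workflows.

`biaxial_gate()` applies the same ordered rules per event, emulating
conventional gating; agreement between the two routes is itself a useful
quality metric. Phase-distribution tests collapse apoptotic and dead into
one category, giving the canonical six categories (df = 5 against two
conditions).

# The synthetic-data generator

The generator emulates the statistical structure the analyses assume, not
the raw sequencing layer (no reads, no count model — the integration
stages consume only intervals, CPM values and (lfc, p, padj) triples).

* **Regulome**: ~1500 genes on a 30 Mb toy chromosome; 1000 true sites
  placed near sampled genes with a 30/40/30 promoter/intragenic/upstream
  position mix; each of 3 ChIP sets detects sites with 90% sensitivity,
  ±20 bp boundary jitter and 15% false peaks; DNaseI is a superset (all
  true sites plus 2000 background open regions). The planted target of a
  site is the nearest-TSS gene of its final summit, so truth is consistent
  with summit-anchored annotation. Signals are lognormal, rounded to 4
  decimals so that peak files round-trip bit-exactly.
* **Expression**: per line, effect `delta * bound * direction + N(0, sd)`
  with default `delta = 0.5`, `sd = 1`, repression (−1); p-values from the
  matching z-test (clamped away from 0), BH-adjusted; the joint table uses
  the pooled z across lines. Defaults give a *weak* per-gene effect that
  is only detectable in aggregate — enrichment appears in the most
  down-regulated bins while individual genes rarely pass the all-lines
  core filter, mirroring the realistic regime; core-recovery demonstrations
  use a strong-knockdown configuration instead.
* **Peak signal**: classes drawn with probabilities 0.35/0.40/0.25
  (R1/R1_ER/ER), log2 CPM ratio means −2/0/+2 with sd 0.4 plus 0.2
  measurement noise; acetylation log2FC means 0/−1/−1.5 coupled to class.
* **Meta-scores**: integer p53 scores ~ round(N(0, 10)) clipped to ±40;
  cell-cycle study counts Poisson with a rate rising on the negative-score
  side; knockdown-like fold change positively coupled to the score across
  its range, fusion-knockdown-like fold change negatively coupled on the
  negative-score side only — the planted asymmetry by which the fusion
  opposes its native counterpart on cell-cycle genes but not on the
  apoptosis arm.
* **CyTOF**: events drawn from condition-specific population × phase
  mixtures; marker means from a built-in table in arcsinh space with
  graded levels 1/3/5 (e.g. cyclin B1 low/mid/high through G1/S/G2-M;
  apoptotic cells are cisplatin-low because membrane-intact cells exclude
  the viability stain); Gaussian noise in transformed space (surface sd
  0.5, cycle sd 0.8), inverse-transformed to the raw ion-count scale and
  clipped at 0. The default fusion condition plants a +10-point S-phase
  excess. The 5-sd low-to-high separation of cycle markers (4/0.8) sits in
  the 4–6 sd range of well-resolved CyTOF markers; at 2 sd, adjacent
  phases that differ in a single marker (G0 vs G1 differ only in pRb)
  would have a Bayes-optimal per-event accuracy near 84%, so no clustering
  method could reach the ~90% recovery that separated mixtures support —
  the default deliberately describes resolvable chemistry.

Identical configurations give byte-identical outputs; truth columns live
in sidecar structures and never enter analysis-facing files.

**What passing on synthetic data does and does not show.** The generator
matches the analyses' *assumptions* (independent Gaussian noise, clean
class mixtures, annotation-consistent site placement). Real data violate
these in known ways — correlated replicates, copy-number and mappability
artefacts in ChIP signal, doublets and acquisition drift in CyTOF, winner's
curse in DE tables — so recovery rates here are upper bounds on real-data
performance; what the tests establish is the *correctness* of the
computations and the calibration of their null distributions, not
field performance.

# Numerical choices and degenerate inputs

* p-values of exactly 0 are clamped to `.Machine$double.xmin` before
  `-log10` ranking; BH inputs must lie in (0, 1].
* Two-sided Fisher sums all tables with probability ≤ the observed
  probability × (1 + 1e-7), the standard tolerance for ties.
* Rank bins and ranked-peak bins are equal-size ± 1 with remainders going
  to the lowest bins; ties always break by identifier so results are
  order-independent.
* Empty enrichment bins yield p = 1 rows with a warning; singleton CI bins
  report the mean with NA intervals; empty GMT sets are legal (two-field
  lines).
* SOM nodes that receive no neighborhood mass keep their previous
  codebook; fewer events than nodes is an error suggesting a smaller grid.
* Quantile scaling of a constant marker maps to 0 rather than dividing by
  zero.
* `summit_window()` clips at position 0 only; chromosome-end clipping is
  the caller's concern since lengths are not tracked.

# Problem sizes

The shipped tests and the acceptance script run at deliberately moderate
scale — 1000 true sites on a 30 Mb chromosome, 1500-gene DE tables, 2000
signal peaks, 19,148 meta-scored genes, 20,000 CyTOF events on a 10×10
grid, 500-permutation GSEA nulls with 200 replicate draws — sizes at which
every Monte-Carlo check is stable across seeds while the entire suite
completes in a few minutes on a laptop.

# Known limitations

* Nearest-gene annotation considers TSS distance only; enhancer-target
  maps (Hi-C, eQTL) are out of scope.
* The three-way peak classification is a ratio cutoff; if the underlying
  study used a statistical test for Fig-4c-style classification, class
  boundaries would differ near the threshold.
* GSEA p-values are permutation-based only (no multilevel refinement) and
  single-set; multi-set FDR is out of scope.
* The SOM uses a fixed rectangular grid with Gaussian neighborhoods;
  toroidal grids and growing maps are not implemented.
* Population rules assume upstream gating on viable CD45+ singlets; the
  CD45 marker itself cannot be used as a contrast after per-marker
  quantile scaling.
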