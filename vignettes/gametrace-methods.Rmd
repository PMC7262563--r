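---
title: "Tracing gamete transcripts and sperm chromatin states: models and methods"
author: "gametrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing gamete transcripts and sperm chromatin states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

Mature sperm retain nucleosomes at a small fraction of the genome, and the
retained nucleosomes at promoters carry informative histone marks: active
H3K4me3 and repressive H3K27me3. Sperm also carry RNA. `gametrace`
implements an integrative analysis connecting the two: which transcripts are
specific to sperm, which are shared with the oocyte, what chromatin state
their promoters carry in sperm, and what becomes of both the transcripts and
the marks across preimplantation development, the three germ layers, adult
tissues, spermatogenesis, and tumors.

The pipeline has five analysis stages plus a synthetic-data generator:

1. **Gamete classification** (`classify_gamete`). A transcript is called
   expressed in a sample when its TPM reaches a threshold (default 1 TPM;
   the underlying studies publish no numeric cutoff, so this is an explicit,
   configurable default). Within each gamete a transcript must be expressed
   in *all* donor replicates to count as consistently expressed, and in
   *none* to count as absent. Sperm-specific (Sp) means consistent in sperm
   and absent in oocyte; oocyte-specific (Oc) is the mirror image; SpOc
   means consistent in both; NotExpressed absent in both; anything else —
   any strict partial replicate pattern — is miscellaneous (Misc) and
   excluded downstream. Whether "consistent" should mean all replicates or
   a majority is genuinely open; we default to the all-replicates rule
   because it makes Misc a well-defined complement of the four clean
   categories, and expose `min_fraction`-style relaxation through the flag
   matrix, which callers can pool before classification.

2. **Promoter chromatin states** (`promoter_windows`, `signal_matrix`,
   `cluster_promoters`, `label_clusters`). Promoters are ±10 kb windows
   around the TSS in 100 bp bins, oriented in the direction of
   transcription. Coverage is binned by per-base averaging, scaled to
   counts-per-million by the track's total signal, and transformed as
   log2(1+x); the normalization the original ChIP processing used is not
   recoverable from the text, and CPM+log2 is the conventional default.
   K-means (Lloyd's algorithm, k-means++-style initialization, 10 restarts,
   fixed seed) runs on the concatenated per-bin-standardized [K4 ‖ K27]
   profile vector, so peak shape and breadth inform the clusters, not just
   total signal. With `k = "auto"`, k between 2 and 6 is chosen by mean
   silhouette width on a subsample. Clusters are labeled by comparing their
   mean central (2 kb) signal per mark against promoter-wide quantiles:
   bivalent if K4 ≥ q50(K4) and K27 ≥ q75(K27); else high-K4 if
   K4 ≥ q75(K4); else low-K4 if K4 ≥ q50(K4); else K4⁻K27⁻.

3. **Expression dynamics** (`aggregate_stages`, `call_trajectory`,
   `panel_specificity`). Stage grids are organism properties: the human
   preimplantation grid runs zygote → late blastocyst with the zygotic
   genome activation (ZGA) window at the four- to eight-cell transition;
   mouse ZGA is one stage earlier (two- to four-cell). A transcript is
   `zga_activated` when silent before the window and induced at least
   `threshold × fold` from it onward; `early_then_degraded` (the shared
   maternal/paternal transcript-degradation shape, SpOc-TD) when present
   through the ZGA start, non-increasing from it (10% tolerance), and
   ending at least `fold` below its early maximum; flat patterns require a
   pseudocounted max/min ratio below `fold`. Stage specificity (peak
   Z ≥ 1.5, all others < 0.5, on log2(TPM+1) stage means) is an invented
   numeric stand-in for a visual heatmap criterion, and is exposed as
   parameters.

4. **Enrichment** (`hypergeom_test`, `term_enrichment`, `scan_pwm`,
   `motif_enrichment`). Term enrichment is the one-sided hypergeometric
   over-representation test with Benjamini–Hochberg FDR across all terms
   with a nonempty universe intersection (zero-overlap terms participate in
   the FDR but are dropped from the report). Motif scanning is a plain
   log2-odds scan of ±250 bp promoters on both strands against a base
   background, with a hit threshold at 80% of a PWM's maximum attainable
   score; motif enrichment counts promoters-with-≥1-hit (binary), keeping
   the hypergeometric model exact. The enrichment background defaults to
   all classified promoters outside the query category; the original
   background is unstated, so this choice is explicit and overridable.

5. **Tumor deregulation** (`cohort_zscore`, `log_fold_change`,
   `deregulation_call`, `normal_source_merge`). Per gene and cancer type:
   the tumor-vs-normal Z score on log2(TPM+1) with Welch-style pooling
   (cohort sizes are very unequal once consortium normals substitute for
   missing matched normals), the difference of mean log2(TPM+1) as log2
   fold change (+1 pseudocount keeps zero TPM defined), a Wilcoxon
   rank-sum test (normal approximation, tie-corrected) with BH-FDR across
   genes within each cancer code, and a call of up/down when
   |log2FC| ≥ 1 and FDR < 0.05. "Deregulated" has no published numeric
   definition; this rule is our explicit stand-in and both thresholds are
   parameters. The pan-cancer count is the number of codes with a
   non-`none` call. Batch correction between matched and fallback normals
   is out of scope; provenance is recorded per sample so users can
   stratify.

# The synthetic-data generator

All tests run against `simulate_bundle()`, which emulates the statistical
structure of the public datasets the analysis was designed for, with truth
labels planted per transcript. Its defaults are the study conditions of the
test suite: 1200 transcripts (80 per biotype × gamete-category cell), two
donor replicates per gamete, a 1 TPM expression threshold, and seed 7.

**Expression.** Noise is log-normal on the log2(TPM+1) scale (the pipeline
starts at TPM, so count-level realism is unnecessary): sd 0.5 for expressed
gamete cells, 0.1 for silent ones, 0.15 for stage/panel samples. Draws are
clamped to the correct side of the threshold in gametes so the planted
on/off contract is exact; with all noise at zero a cell's TPM equals its
configured mean exactly. Sperm expression means depend on the promoter
state (high-K4 6.5, low-K4 5, bivalent 4, K4⁻K27⁻ 3.5 on the log2 scale),
planting the expression–chromatin correlation the analysis must recover,
and shared transcripts are planted higher in oocyte than sperm. Misc
transcripts get exactly one expressed replicate in one gamete. Trajectory
classes follow category: Sp activates at ZGA, Oc and SpOc-lincRNAs carry
the early-then-degraded shape, SpOc coding stays flat-on, the rest
flat-off. The spermatogenesis panel plants round-spermatid-restricted
expression for high/low-K4 sperm-expressed transcripts and meiotic-stage
expression for the others.

**Chromatin.** Coverage is piecewise-constant at 200 bp with Gaussian
promoter peaks: narrow K4 (sd 1 kb), broad K27 domains (sd 4 kb), background
1, amplitudes 30 (high-K4), 8 (low-K4), 10+20 (bivalent) — separable but
overlapping. Per-transcript amplitudes carry log-normal noise (sd 0.2 log2
units) and every interval carries small multiplicative noise (sd 0.01),
which keeps the quantile thresholds strictly ordered (a perfectly flat
background makes "≥ quantile" degenerate at exact ties).

**State proportions are category-dependent, and this matters.** Promoter
H3K4me3 in sperm tracks sperm expression, so sperm-expressed transcripts
(Sp, SpOc) get a balanced mix of marked states — thirds over
high/low/K4⁻K27⁻ for lincRNAs, quarters including bivalent for coding
transcripts, mirroring the several comparably sized clusters seen among
sperm-expressed promoters — while promoters of transcripts absent from
sperm are 75% unmarked. The two populations play different roles: clustering
operates on the sperm-expressed subset, where balanced groups give
silhouette-based k selection a clean optimum at the planted number of
states, while the labeling quantiles are taken promoter-wide
("genome-wide"), where the unmarked majority places q50 between the
background and low-K4 populations and q75 between low-K4 and high-K4.
With a single balanced population these two requirements contradict each
other — the median falls inside the low-K4 population and the labeling rule
misassigns it — which is why the generator distinguishes them.

**Germ layers and tissues.** A retention map per
(category × biotype × state × compartment) controls which sperm marks
survive: by default sperm-specific high-K4 and low-K4 promoters lose their
K4 (background only) in all three germ layers and the derived tissues,
bivalent coding promoters retain both marks, and everything else retains
its sperm configuration.

**Tumors.** 26 cancer-type codes with 30 tumor and 20 normal samples per
code, log-normal expression (sd 0.5) around a shared baseline, and one
focal sperm-lincRNA gene shifted by ±2 log2 units in 21 of the 26 codes
(up in two-thirds of them). Cohort sizes were chosen by a power argument:
the Wilcoxon normal-approximation p-value has a floor of roughly 2×10⁻⁴ at
ten-vs-ten, which cannot clear a BH correction across a 400-gene panel, so
smaller cohorts would make the planted design unrecoverable by any method.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: read-level sampling noise and mappability
artifacts, overlapping transcripts and ambiguous read assignment
(the original analyses restrict to intergenic lincRNAs for exactly that
reason), peak-shape diversity beyond Gaussians, inter-donor biological
variability beyond log-normal spread, tumor purity and copy-number effects,
and batch structure between matched and consortium normals.

# Numerical choices

* **Variance-floored standardization.** Before clustering, each bin is
  centered and scaled, but bins whose standard deviation falls below the
  mean bin sd are scaled by that floor instead of their own sd. Flank bins
  carrying only background noise would otherwise be amplified to unit
  variance, and with ~350 of 400 bins uninformative their accumulated
  noise distance dominates the silhouette and drives k selection toward
  merging genuinely distinct marked states.
* **Quantile reference.** `label_clusters` and `trace_states` compute
  thresholds from a caller-supplied reference (the full promoter
  population in the pipeline); labeling a subset against its own quantiles
  is supported but not recommended, because the rule presumes an
  unmarked-majority reference.
* **Ties and degenerate inputs.** Constant rows Z-score to zero rather
  than NaN; an all-identical profile matrix returns a single cluster with
  a warning; empty coverage reads as an empty track whose zero library
  size is rejected at normalization time; windows overhanging a chromosome
  start keep their out-of-range bins as flagged zeros so matrices stay
  rectangular.
* **Boundary sensitivity of persistence tracing.** A cluster whose central
  signal sits exactly at a quantile threshold (in the default germ-layer
  design, SpOc low-K4 promoters sit at q75 of the compartment's K4) can
  relabel either way under resampling; the traced statuses asserted by the
  test suite are the ones with designed margins (all sperm-specific
  clusters, and shared high-K4/bivalent/unmarked clusters).
* **Problem sizes.** The default test conditions — 1200 transcripts, ±10 kb
  windows at 100 bp bins, 26 tumor codes at 30/20, 1000-permutation
  calibration at a 3000-gene universe — were chosen as the smallest sizes
  at which every planted effect is statistically identifiable with
  comfortable margins.

# Known limitations

The reader accepts bedGraph (and piecewise-constant text generally) but not
bigWig; coverage tracks must be pre-converted. The k-means/silhouette
auto-k is a heuristic: elongated or strongly unbalanced clusters can favor
merging, and the reported silhouette profile should be inspected when the
chosen k is surprising. GO-style term sets are flat (no DAG propagation).
The motif scanner is a known-motif tool, not a de novo discovery method.
Deregulation calls ignore purity, copy number and batch; they are
screening-level statistics, not causal claims.
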