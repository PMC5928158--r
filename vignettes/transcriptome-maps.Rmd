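---
title: "Integrated quantitative transcriptome maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated quantitative transcriptome maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trisomap)
```

## The problem

Trisomy 21 places more than 400 genes in three copies. The simplest
gene-dosage model predicts a 3:2 (1.5x) trisomic/euploid expression ratio
for every triplicated gene, but real data show dosage-escaping genes on the
trisomic chromosome and dysregulated genes elsewhere in the genome.
Individual microarray studies disagree, largely because of platform,
tissue and statistical differences. trisomap implements a meta-analytic
answer: integrate many heterogeneous expression datasets into a single
quantitative transcriptome map -- one consensus linear expression value per
locus per condition -- then compare the trisomic pool (A) against the
euploid pool (B) locus by locus and window by window.

## The integration model

**Intra-sample normalization.** Raw intensities at or below zero are first
thresholded to 95% of the sample's minimum positive value
(`threshold_nonpositive()`): an undetected transcript is treated as "just
below the detection floor" rather than zero, so A/B ratios remain defined
and genuine strong over-expression is not erased by a zero numerator. Each
value is then expressed as a percentage of the sample mean
(`intra_sample_normalize()`), the classic global normalization; every
sample leaves this stage with mean 100. The order -- threshold, then
rescale -- treats thresholding as a raw-intensity repair, so the sample
mean is taken over the repaired values.

**Scaled quantile normalization.** Platforms probe very different numbers
of features (the pipeline accepts 5,000-60,000; arrays outside that range
are rejected at load as atypical designs), so classical full-vector
quantile normalization does not apply. Instead, each sample's empirical
quantile function is evaluated by linear interpolation on a fixed grid of
`n_quantile_points` (default 1001) probabilities $k/(n-1)$, and the
reference is the pointwise mean of these curves over *all* samples of the
analysis (`build_quantile_reference()`). Each value is then replaced by the
reference quantile at its own fractional within-sample rank, ties sharing
the mean rank (`scaled_quantile_normalize()`). Three properties motivate
this construction: it is well defined for unequal feature counts; it
reduces exactly to classical quantile normalization when all samples share
the feature count equal to the grid size (a tested oracle); and it removes
any smooth monotone intensity-dependent platform distortion, because such a
distortion changes no within-sample ranks. The reference is deliberately
built jointly over pools A and B: per-pool references would normalize away
the pool-level shifts the differential map is supposed to measure.

**Pooling.** The consensus value of a locus in one pool is the arithmetic
mean of all its (probe, sample) records (`pool_loci()`). Records -- not
samples -- are weighted equally; a sample with three probes for a gene
contributes three records. The alternative (mean of per-sample means) is a
defensible variant, but the record-weighted mean matches the "mean of all
available values" definition and keeps record and sample counts separately
auditable. Loci measured in fewer than `min_samples_per_locus` (default 3)
distinct biological samples are excluded per pool.

**Differential map and dosage bands.** For loci present in both pools the
map reports $R = \bar{x}_A/\bar{x}_B$ (`differential_map()`). Ratios are
banded at two-decimal boundaries: over $\ge 1.30$, neutral $0.77$-$1.29$,
under $\le 0.76$ -- the 3:2 and 2:3 dosage expectations widened to absorb
natural variability. Because the bands are defined at 2 d.p., the ratio is
rounded half-up to 2 d.p. before comparison (1.295 is over); plain IEEE
round-half-even would misplace boundary values.

## Segment calling

Windows of 500 kb, shifted by 250 kb, are tiled from position 1 of every
chromosome; a locus belongs to a window if its *start* coordinate falls
inside, so each locus is counted twice regardless of gene length (except
within one window of a chromosome end). A segment's value is the mean of
its members' values. In differential maps the per-locus value used for
flagging and scoring is the log2 ratio, making the over- and
under-expression tails symmetric; in single-pool maps it is the consensus
mean.

Calling proceeds tag-first, test-second:

1. Loci in the top/bottom `extreme_percentile` (default 2.5%) of the map
   are flagged (`flag_extreme_loci()`), using linear-interpolation
   percentiles with inclusive thresholds. A tie group lying exactly at the
   threshold joins only if the tail stays within its nominal size; a
   constant map therefore flags nothing.
2. A segment is a candidate in one direction if it holds at least
   `min_extreme_genes` (default 3) same-direction flagged loci *and* its
   own value lies in the corresponding 2.5% tail of all non-empty segment
   values. One percentile knob serves both the gene and the segment
   condition.
3. Candidates are tested with the hypergeometric upper tail
   $P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$ -- the chance that
   $k$ of the segment's $n$ genes are flagged when $K$ of $N$ genes are
   flagged genome-wide and placement is random.
4. Benjamini-Hochberg correction is applied across the candidates of each
   direction within a map; a segment is called at $q < 0.05$.
5. Chains of consecutive same-direction calls whose gene sets overlap by
   Jaccard > 0.5 are collapsed to their most extreme member (ties: smaller
   q, then leftmost start) (`deduplicate_segments()`).

**Single-gene mode** (`single_gene_mode()`) reruns the machinery with a
25 kb window, half-window shift (12.5 kb, by analogy with the map-mode
default; only the window and gene minimum are prescribed) and a one-gene
minimum. Since 25 kb is well under typical human gene length, a called
window usually holds one gene. When it holds several, the call is
attributed to a flagged gene only if its |log ratio| is strictly the
largest in the window -- the "prevails" rule made precise.

**Per-chromosome summary.** `chromosome_mean_ratio()` reports, per
chromosome, the ratio of the pool means over its comparable loci and the
resulting rank; in a trisomy the trisomic chromosome is expected first.

## qPCR validation arithmetic

`delta_delta_ct()` implements $2^{-\Delta\Delta Ct}$ with
$\Delta Ct = Ct_\mathrm{target} - \overline{Ct}_\mathrm{ref}$ per pool;
multiple reference genes are combined by the arithmetic mean of their Cts
(equivalently the geometric mean of relative quantities -- the combination
rule is not otherwise constrained). `correlate_ratios()` computes the
Pearson r between map-expected and qPCR-observed ratios with the
t-distribution p-value on n - 2 degrees of freedom. The package ships a
published 13-gene fibroblast validation panel and a 6-tissue SOD1 dosage
panel as plain-text fixtures; `run_validation()` recomputes the expected
ratios from the per-pool values and the correlation from the panel columns.

## The synthetic-data generator

`synthetic_config()` / `generate_annotation()` / `simulate_pools()` emulate
the statistical structure the analysis assumes, so every stage is testable
without downloads:

* a designated trisomic chromosome whose dosage-sensitive genes sit at mean
  ratio `dosage_factor` (1.5), with an `escape_fraction` (default 0.3) at
  ratio 1;
* trans-effects: 25 + 25 non-trisomic genes at 1.5 / 0.67;
* optional planted gene-dense windows whose members share a common ratio;
* per-gene lognormal baselines (meanlog log 100, between-gene sigma 1),
  multiplicative lognormal record noise (sigma 0.2 -- multiplicative
  because intensity noise scales with signal and must preserve
  positivity);
* three platforms (6000/5500/5000 features) covering 90/70/50% of genes
  with 1-3 probes each plus unassigned filler probes, each with a smooth
  monotone power-law intensity bias ($x^\gamma$, $\gamma$ = 0.85/1.15/1.0)
  -- exactly the distortion scaled quantile normalization is meant to
  remove -- and mixed emission formats (linear/log2/ln);
* 10 biological samples per pool, platforms assigned round-robin.

The default genome has six chromosomes with the trisomic one smallest (120
of 1,800 loci, about 7%): the trisomic chromosome must be a small fraction
of the map, as it is in reality, because quantile normalization equalizes
whole distributions and would visibly shrink dosage ratios if a quarter of
all loci carried them. Everything is a deterministic function of the seed;
written datasets are byte-identical across reruns.

What the generator does *not* emulate: probe-level sequence effects,
within-pool biological heterogeneity beyond lognormal noise, correlated
(chromatin-domain) dysregulation, RNA-seq counts, and missing-value
structure beyond unassigned probes. Passing the simulation benchmarks
therefore shows the pipeline recovers the structure it models, not that it
is robust to everything real arrays do.

## Numerical choices and degenerate inputs

* Percentiles everywhere are `stats::quantile` type 7 (linear
  interpolation), matching the flagging definition.
* Half-up rounding (with a 1e-9 guard) is used wherever a published
  2 d.p. boundary is compared.
* Constant maps flag nothing and call nothing; empty windows are retained
  but can never be candidates; an all-non-positive sample and an empty
  pool are hard errors naming the stage.
* A locus comparison requires presence in both pools; a map with no shared
  loci is an error rather than an empty result.
* Benjamini-Hochberg is computed over candidates only, per direction, per
  map -- the tag-first ordering means the test population is "segments
  that look extreme", which the q-values condition on.

## Benchmark scale

The packaged benchmarks run at desk scale, chosen so a full suite completes
in about a minute: 1,800-gene default genomes, 5,000-locus planted-segment
maps over 20 seeds, 200 null maps, and 100 end-to-end pipeline runs for
dosage recovery. At these sizes the dosage-recovery band [1.40, 1.60] is
met with wide margin (observed medians cluster near 1.44: joint quantile
normalization of a 7%-trisomic genome retains a slight conservative bias,
about 3% of the 1.5 signal).

## Known limitations

* Probe-to-symbol resolution is taken as given via platform annotation
  tables; no identifier-history resolution is attempted, and symbols absent
  from the genome annotation are dropped (with counts logged).
* Only the mean is implemented as the consensus summary; a rank-based
  summary would be more robust to heavy-tailed platforms.
* The record-weighted consensus mean lets probe-rich platforms dominate a
  locus; a config switch for sample-weighted means is a reasonable future
  addition.
* Segment significance inherits the hypergeometric independence
  assumption; spatially correlated expression (domains) inflates calls and
  is intentionally not modelled.
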