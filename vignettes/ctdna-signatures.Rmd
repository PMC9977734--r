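---
title: "Copy-number signatures from plasma shWGS: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number signatures from plasma shWGS: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctDNAsig)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical conventions.

# The measurement model

Shallow whole-genome sequencing of plasma cell-free DNA yields per-bin
(500 kb) log2 copy ratios, segmented upstream (ichorCNA for plasma, CNVkit
for tissue). The observed plasma signal is a mixture: at tumor fraction
$tf$ and true tumor copy number $c$, the linear ratio of a bin is

$$ r = tf \cdot \frac{c}{2} + (1 - tf), $$

because the non-tumor cfDNA background is diploid. Raw log2 ratios
therefore shrink toward 0 as $tf$ falls, and anything computed from them
correlates with tumor fraction. The package works at the segment level on
two scales:

* **Unadjusted**: the segment's mean log2 ratio as segmented upstream.
* **TF/ploidy-adjusted**: $\log_2(\hat c / \psi)$, where $\hat c$ is the
  TF-corrected absolute copy number reported by the upstream caller and
  $\psi$ the average tumor ploidy. A segment at the tumor's average ploidy
  maps to exactly 0, and the $tf$ dependence cancels. (The upstream
  formula is printed as a ratio of a "logR" copy number to ploidy inside a
  log2; the only dimensionally coherent reading — the one implemented —
  is the log2 of the corrected *absolute* copy number over ploidy.
  Corrected copy numbers of 0 are floored at $2^{-10}$ before the log.)

Adjustment requires $tf > 0$; tumor-free samples are excluded earlier by
the **TF gate** (`tfGate()`, inclusive cutoff, default 3% — the detection
threshold of the upstream TF estimator). Whether gene means should be
taken in log2 or linear space is not specified upstream; log2 space is
used throughout.

# From segments to signature scores

1. **Gene level.** Every gene takes the value of its overlapping segment;
   a gene spanning $k > 1$ segments gets the overlap-length-weighted mean
   (deterministic, and robust to breakpoint placement). Genes with no
   overlapping segment are flagged missing, never silently zeroed.
2. **Canonical segments.** Each of the scheme's canonical segments (514 in
   the published resource) is the arithmetic mean of its member genes with
   observed values. A segment with no observed gene is imputed neutral
   (0) and flagged; the per-sample missingness report keeps the imputation
   auditable, and a signature whose weighted segments are >50% imputed
   carries a low-confidence flag.
3. **Scores.** A signature score is the plain weighted sum
   $\sum_i w_i x_i$ — the linear predictor of the published Elastic-Net
   models. It is *not* divided by $\sum_i w_i$ (unstable with mixed-sign
   weights); an optional normalization by $\sum_i |w_i|$ is provided, and
   no intercept is added because none was published. All downstream use is
   rank/threshold-based, so any positive rescaling is immaterial.

**Altered-segment counts** use the published cutoffs with strict
inequalities ("above"/"below"): gains > +0.07 and losses < −0.07 on the
unadjusted scale, > +0.32 and < −0.42 adjusted.

# Subtype discovery and classification

**Consensus clustering** (`consensusCluster()`): 1000 resamples of 80% of
samples (no feature subsampling), average-linkage hierarchical clustering
on the 1 − Pearson-correlation distance between sample score profiles;
consensus(i, j) = co-clustering count / co-sampling count. The number of
clusters comes from the relative delta-area criterion on the consensus
CDF, refined by an ambiguity check: k is acceptable when its relative gain
in CDF area is ≥ 0.1 *and* its proportion of ambiguous consensus entries
(PAC, entries in (0.1, 0.9)) is ≤ 0.05; the largest acceptable k wins,
falling back to the largest gain if none qualifies. The refinement is
needed because pure delta-area misreads two common geometries: a strong
two-supergroup hierarchy makes intermediate k unstable (small gain) while
the finer true k is perfectly stable, and isolated outlier samples claim a
cluster slot, shifting true structure from k to k+1. For the second
reason, final clusters smaller than 5% of the cohort are folded into the
cluster with which they share the highest mean consensus, and the reported
k is the effective cluster count. On synthetic cohorts this selects the
generative k reliably for pattern separations of ≥ 5 noise SDs; on
marginal cohorts it errs toward fewer clusters (one of six cohort seeds
undershoots to k = 2), never toward spurious ones.

Cluster labels are conventionally renumbered 1..k by descending mean of a
designated luminal-A-like signature (`relabelClusters()`), so cluster 1
carries the best-prognosis semantics; this is a labeling convention, not a
claim.

**Signature selection** uses multiclass SAM: the moderated statistic
$d_j = \sqrt{MS_{between,j}} / (s_j + s_0)$ with pooled within-class
$s_j$; without moderation this is $\sqrt F$ of the one-way ANOVA. The
published analyses do not print SAM internals, so canonical conventions
are made explicit: $s_0$ is the 5th percentile of the $\{s_j\}$,
permutations shuffle class labels globally (sign flips for the paired
two-class test), the null proportion $\pi_0$ is fixed at 1 (conservative),
q-values are monotonized in $|d|$, and the default is 1000 permutations
(≥ 100 required; with very small groups — e.g. 3 vs 3 — the attainable
permutation FDR is bounded above 5%, so selection needs more samples, not
a looser threshold).

**Nearest-centroid model**: centroids are per-cluster means over the
SAM-selected signatures only (the published predictor used "the selected
gene list"); assignment is by Euclidean distance with ties going to the
lowest-numbered cluster. **Cluster subdivision** implements the printed
rule — the within-cluster average-linkage dendrogram is cut into its two
top branches, and the split is accepted only when both branches have ≥ 20
samples and within-branch mean pairwise correlation > 0.75; an undivided
cluster is a valid outcome. Note the rule is about coherent subgroups: a
homogeneous cluster with a strong shared pattern can satisfy the
correlation gate, which is a limitation of the published rule itself.

# Clinical statistics

Two-sided tests throughout, α = 0.05. Kaplan–Meier medians are the first
time the survival step function reaches ≤ 0.5 (NA if never). Cox models
use the Efron tie approximation and Wald confidence intervals (the source
analyses do not state their choices; these are the standard defaults of
the survival ecosystem). Non-convergence, separation, and constant or
aliased covariates return an explicit `"failed"` status rather than an
error, so repeated-fit experiments can count failures. Tertile cutpoints
are the 1/3 and 2/3 empirical quantiles; cross-cohort validation freezes
cutpoints in the training cohort and reapplies them verbatim
(`applyCutpoints()`). Contingency tables use Fisher's exact test when any
expected cell is < 5 and the chi-square test (no continuity correction)
otherwise. ROC AUC is the rank-sum form with ties counted half.

# What the synthetic generator emulates — and what it does not

The study's patient data are not deposited, so every analysis is exercised
on synthetic cohorts whose *structure* matches the assumed data:

* **Genome scheme**: 22 synthetic chromosomes tiled by 500-kb bins,
  partitioned into canonical segments each carrying member genes. The
  default reduced scheme (120 segments, 600 bins, 360 genes) keeps tests
  fast; `n_segments = 514` generates the published geometry, on which the
  RB-LOH-like signature is padded with low-weight scattered segments to
  its published 236-segment size.
* **Archetypes**: deterministic copy-number landscapes for four clusters
  (plus 2A/2B variants and a diploid healthy profile), painted on
  chromosome arms in the spirit of the reported biology — cluster 3
  carries the RB-LOH-like pattern (gains 2p/3q/8q/20q/21q, deletions
  2q/4q/5q/12q/13q/15q/17p), cluster 2 a luminal-B pattern with the
  16p+/16q− axis, cluster 4 a HER2-amplicon-like pattern, cluster 1 a
  low-burden luminal-A genome. Amplitudes and arm choices are the
  package's own design, fixed once; they are *not* estimates of the real
  landscapes.
* **Observation model**: the linear mixture above plus i.i.d. Gaussian
  bin noise (default SD 0.1 log2 units); mixture ratios are floored at
  $2^{-10}$ with a warning (homozygous-deletion edge). Segments merge
  adjacent equal-truth bins. The corrected copy number is back-computed by
  inverting the mixture rule on the observed segment mean,
  $\hat c = 2\,(2^{obs} - (1 - tf))/tf$, clamped to [0, 8] copies as a
  bounded-state caller would report. Noiseless input recovers the truth
  exactly (so dilution closed-form identities hold), and noisy input
  carries the realistic low-TF noise amplification — without this, the
  adjusted pipeline would be noise-free within an archetype and every
  within-cluster statistic degenerate.
* **Subtype cohort** (`makeCohort()`): default 200 samples, 50 per
  archetype, TF uniform on (0.05, 0.6) with cluster 1 drawn from the lower
  portion (upper bound 0.45; the low-proliferation cluster shows lower TF
  in plasma). Archetype landscapes are kept crisp by default
  (`alteration_dropout = 0`); outcomes follow exponential proportional
  hazards on standardized scores (default: RB-LOH-like log-HR 0.5 per SD,
  baseline 0.08/month, censoring 0.02/month) with per-cluster response
  rates (defaults 52.7/34.0/7.1/16.7% for clusters 1–4, used as generator
  parameters).
* **Prognostic cohort** (`makePrognosticCohort()`): a single-disease
  continuum for the survival/ablation experiments — each tumor
  interpolates between the luminal and proliferative archetypes with
  burden $u \sim U(0,1)$, each alteration independently retained with
  probability 0.7, and TF lognormal (median 10%, clipped to 3–84%,
  matching treated advanced-breast-cancer plasma). Hazards are tied to the
  *true* RB-LOH-like score, so measured (and ablated) scores estimate the
  prognostic quantity with error; this is the setting in which removing
  20→160 signature segments visibly attenuates the hazard ratio toward 1,
  as the in-silico ablation design expects. On the crisp 4-cluster cohort
  the between-cluster contrast dominates and ablation barely attenuates —
  which is itself informative about when such ablation experiments are
  meaningful.
* **Dilution and downsampling**: `dilutionSeries()` re-simulates a tumor
  at fractions 0.50→0.01 (noiseless mode matches
  $\log_2(f c/2 + 1 - f)$ exactly); `downsampleProfile()` scales bin noise
  by $1/\sqrt{\text{coverage factor}}$ (shot-noise model) — the noise
  magnitudes per coverage are not published, so these defaults are
  calibrated only to reproduce the qualitative rank-order claims.
* **Paired tissue**: tissue truth = concordance-weighted mixture of the
  plasma truth and an independent archetype draw, observed as pure tumor.

Not emulated: read-level data (GC bias, mappability, fragmentomics),
subclonal structure beyond a single tumor fraction, the upstream HMM
segmentation itself (its output format is consumed), and real biological
correlation structure among the 150 signatures (filler signatures are
random). Passing tests therefore certify the pipeline's arithmetic,
calibration and qualitative behavior — not performance on real cohorts.

All randomness flows from one master seed through deterministic
sub-seeds; regenerating a cohort from the same configuration is
bit-identical.

# Numerical conventions and degenerate inputs

* Intervals live in `GRanges` (1-based closed). SEG/ichorCNA/CNVkit files
  are read and written 1-based inclusive as-is; BED input is shifted on
  read. Chromosome names are normalized by stripping `chr`; mitochondrial
  records are dropped, X/Y kept.
* Zero-variance inputs: Pearson correlations return NA with a warning;
  a constant feature has SAM statistic 0; constant covariates fail the
  Cox fit with status, not an error; all-equal scores refuse tertile
  derivation.
* Ties: nearest-centroid ties go to the lowest cluster index; AUC averages
  tied ranks; tertile boundaries are right-closed.
* Score files round-trip through TSV at 17 significant digits; profile
  round-trips are exact at the precision of the written text.

# Problem sizes used in the shipped checks

The test suite runs the full pipeline at the default study conditions
(200-sample cohort, 120-segment scheme) and the ablation experiment on a
140-patient prognostic cohort over the 514-segment scheme with 500
repetitions per removal size; calibration suites use 50–100 simulated
datasets. These sizes were chosen so the complete suite runs in a few
minutes on a single CPU while keeping every statistical check adequately
powered.

# Known limitations

* Automatic cluster-number selection is conservative on marginal cohorts
  (low TF, small landscape differences); inspect the delta-area and PAC
  profiles in the `ConsensusResult` rather than trusting a single number.
* The SAM permutation FDR is conservative ($\pi_0 = 1$) and unreliable
  below ~8 samples per class.
* An assembly mismatch between a gene map and a segmentation profile is
  undetectable at this layer and remains the caller's responsibility.
* The generator's archetypes are stylized; effect sizes measured on them
  (recovery rates, hazard ratios) characterize the pipeline, not breast
  cancer.
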