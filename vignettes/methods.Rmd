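---
title: "Methods: models, parameters and design choices in crcwnt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in crcwnt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crcwnt` analyzes microsatellite-stable colorectal cancers (CRC) that lack
APC-pathway mutations (APCmut−). This vignette records the statistical
models the package implements, the parameters that matter, what the
bundled synthetic cohort generator does and does not emulate, and the
design decisions taken where more than one defensible choice existed.

## Sample classification

Tumors are first filtered: MSI-high samples and samples with more than
`hypermutation_threshold` (default 700) non-silent mutations are excluded,
because hypermutated CRC is a distinct biological entity. The remaining
tumors are APCmut+ if they carry a non-silent *APC* mutation, an *APC*
deep (homozygous) deletion, **or** a non-silent *CTNNB1* mutation, and
APCmut− only if they carry none of these. The three events are
biologically interchangeable routes to constitutive WNT activation, which
is why any one of them suffices for the positive label.

Two boundary choices are deliberate and configurable:

* the hypermutation count uses non-silent mutations only
  (`count_all_mutations = FALSE`), since mutation burdens are commonly
  reported on that scale;
* tumors with *unknown* MSI status are retained with a warning
  (`strict_msi = FALSE`) so that incomplete clinical annotation does not
  silently shrink the cohort; a strict mode excludes them instead.

## Alteration enrichment and mutual exclusivity

The alteration matrix is binary: gene × sample, 1 iff the sample has a
non-silent mutation, deep deletion, amplification, or (for fusion
pseudo-genes such as `PTPRK-RSPO3`) the fusion. Per-gene enrichment
between label groups uses the exact hypergeometric test with the
**probability-mass two-tailed convention**: the p-value sums the
probabilities of all tables (fixed margins) whose probability does not
exceed the observed table's. Two-tailed conventions for Fisher's test
differ across software; this one matches `stats::fisher.test` and is
verified in the test suite against a full-support enumeration oracle.
Odds ratios are the unconditional `ad/bc` with `Inf`/`0` sentinels and a
`zero_cell` flag rather than a continuity correction, so downstream code
can decide how to display them. Genes altered in fewer than `min_altered`
(default 3) samples are dropped — a singleton alteration cannot support a
stable ranking.

Mutual exclusivity of a gene pair is assessed by permutation: each gene's
alteration vector is independently re-assigned to random samples,
preserving its alteration frequency; `p_exclusive` is the (+1
pseudocounted) fraction of permutations with co-occurrence at or below
the observed count. For two genes this null is hypergeometric, which the
tests exploit as an analytic check; the permutation form generalizes to
stratified nulls if ever needed.

## Expression: filtering, normalization, moderated t

Genes with less than 1 count-per-million in **more than half** of the
samples are discarded; a gene at exactly half (even n) is retained, the
strict reading of "more than half". Normalization computes
`log2((count + 0.5) / effective_library_size * 1e6)` with
median-of-ratios (DESeq-style) size factors rescaled to the mean raw
library size. Median-ratio scaling is robust to composition effects from
a handful of highly shifted genes (exactly what planted or real driver
modules produce); `method = "none"` disables it.

Differential expression uses a pooled-variance empirical-Bayes moderated
t. Per gene, the pooled residual variance `s2` has `d = n1 + n2 − 2`
degrees of freedom, and the posterior variance is
`s2_post = (d0·s02 + d·s2) / (d0 + d)`; `t_mod = log2fc / (s_post·sqrt(1/n1 + 1/n2))`
is referred to a t distribution on `d0 + d` df. When the prior is not
supplied, `(d0, s02)` are estimated by matching the first two moments of
the observed `s2` distribution to its scaled-F marginal
(`s2 ~ s02 · F(d, d0)`), solving
`d0 = (2(d − 2) + 4rd) / (rd − 2)` with `r = var(s2)/mean(s2)^2`, and
falling back to `d0 = ∞` (all variances pooled) when the observed spread
does not exceed what `d` residual df alone implies. The limits are exact:
`d0 = 0` reproduces the ordinary pooled t (tested to 1e-10), `d0 = ∞`
pins every posterior variance at `s02`. This captures the substance of
moderated-t analysis without reproducing any particular implementation
bit-for-bit; the contrast is unadjusted for covariates.

## WNT ligand sensitivity and CL1/CL2 clustering

The score is
`WNT_LS = Z[ z(RSPO3) − (z(RNF43) + z(ZNRF3)) ]`,
with both the inner per-gene z-scores and the outer standardization taken
over the full scored population — all tumors **plus normals**, so that
normal colon anchors the scale. All standard deviations are sample
(n − 1) SDs; the package uses one convention throughout rather than
exposing a population/sample toggle in results. Constant gene expression
makes a z-score undefined and raises an error rather than producing NaNs.
The companion quantity `max_wnt` is the sample's maximum expression over
the WNT ligand family list (all 19 human WNT symbols by default,
intersected with the filtered genes; fully configurable).

APCmut− tumors are clustered on the DE genes (`p_adj < 0.05`) with
distance 1 − Pearson correlation between samples and average linkage, cut
at k = 2. Genes are mean-centered first: without centering, sample–sample
correlations are dominated by shared gene baselines (all pairs ≈ 0.99)
and the subtype signal drowns. Cluster naming is made reproducible by
orientation: the cluster with the higher mean WNT_LS is CL2 (ties go to
the larger cluster). Linkage and distance are configurable
(`ward.D2`/euclidean) since no single choice is canonical for
transcriptomic subtyping; 1 − Pearson with average linkage is the
conventional default.

## Preranked gene set enrichment

Genes are ranked by the moderated t of the CL1-vs-CL2 contrast. The
enrichment score is the classic weighted Kolmogorov–Smirnov statistic:
walking the ranking, set members add `|t|^exponent` (normalized by the
member sum), non-members subtract `1/(N − Nh)`; the ES is the signed
maximal deviation. The implementation evaluates only the hit positions
(the running sum is monotone between hits) and matches a brute-force
full-profile oracle to 1e-12 and `fgsea::calcGseaStat` to 1e-10 in the
tests. The null is **gene-label permutation** — random same-size position
sets in the fixed ranking — with one shared null per distinct set size.
`NES = es / mean(|null ES| of the matching sign)` and the p-value is the
matching-sign tail frequency with a +1 pseudocount, so p is never exactly
zero. Ranking ties are broken by gene name for determinism.

## Immune deconvolution

Bulk linear-scale expression (`2^logcpm`) is regressed on a non-negative
cell-type signature matrix by non-negative least squares, per sample; the
absolute immune score is the coefficient sum, a conceptual analogue of
absolute-mode deconvolution scores. NNLS on a user-supplied signature is
a deliberate, transparent stand-in for heavier machinery (support-vector
regression with batch correction): linear mixing is the common core of
all such methods, and with a full-rank signature the solver recovers
noiseless mixtures to 1e-8. Deconvolution happens on the linear scale
because mixing is linear in transcript abundance, not in log space.

## Differentially methylated regions

Per probe, a Welch t on beta values between groups with BH adjustment
across probes. Significant probes (`p_adj < 0.05`) with a consistent
delta-beta sign are merged into regions when consecutive significant
probes lie within `max_gap` (default 1000 bp); runs shorter than
`min_probes` (default 3) are dropped. A non-significant probe *inside*
the gap does not break a run — the region concept is spatial, not
index-contiguous. Regions are annotated to the member-probe gene with the
smallest minimum p, and per-group region methylation is the mean beta
over the region's significant probes, applied per sample for the
correlation analyses. Coordinates are 0-based half-open everywhere
(BED-compatible; a region whose last probe sits at position p ends at
p + 1). This window-merge caller preserves the DMR concept at package
scale; kernel-smoothed callers remain out of scope.

## Age-of-onset screen

For each gene, APCmut− samples are split at the median expression
(strictly-above → high; ties and the odd middle sample → low,
deterministically) and the two groups are compared by a logrank test with
**age at diagnosis as the event time and no censoring** — every patient
was diagnosed, so every "event" is observed. This is survival machinery
repurposed as a distribution-comparison screen; with zero censoring the
Kaplan–Meier estimator reduces exactly to one minus the empirical CDF,
which the tests verify against both the closed form and a generic KM
implementation. The logrank statistic is the standard
`(Σ(O1 − E1))² / ΣV` over distinct event times with hypergeometric
moments, verified against `survival::survdiff`. Genes with more than 20%
missing ages or a degenerate split are skipped. The chi-square reference
is asymptotic: calibration is checked at 100 + 100 samples per group,
where the 1-df approximation is accurate; at very small n the test is
slightly anti-conservative, a known property of the statistic rather
than of this implementation. The scan runs on filtered genes only.

## The synthetic cohort generator

`generate_cohort()` draws a full multi-omic cohort under the default
study conditions: 63 APCmut− and 362 APCmut+ tumors plus 12 normals,
2000 genes, 5000 probes, mean age at diagnosis 61.4 vs 66.4 years
(SD 10, truncated at 25). Counts are negative binomial (dispersion 0.1)
around per-gene log2 baselines with log-normal library sizes; betas are
beta-distributed (precision 60) around planted probe means; ~40
background mutations per tumor are scattered over filler genes.

Planted structure and the one-time choices behind the magnitudes:

* **CL1/CL2**: half of APCmut− is CL2 (`cl2_fraction = 0.5`).
* **RNF43**: the APCmut− group mean log2FC is `rnf43_log2fc = −0.98`,
  allocated 1.5× to CL2 and the remainder to CL1, so CL2 is the
  low-RNF43 subcluster while the group-level contrast carries the full
  effect — RNF43 is the designed top DE gene, mirroring its role as the
  single most discriminating transcript in this tumor group.
* **Drivers**: within CL2, PTPRK-RSPO3 fusions (12% of APCmut−), RNF43
  truncating mutations (11%) and BRAF V600E (10%) are assigned by
  sampling *without replacement*, so fusion and RNF43 mutation never
  co-occur by construction. Fusion carriers get a stronger RSPO3 shift
  (+3 vs +1.5 log2) and −1 log2 on all WNT ligands, giving them the
  highest WNT_LS but the lowest ligand expression.
* **Oxphos module**: 40 genes at +1 log2 in CL1 — strong enough that the
  module separates CL1 in clustering and preranked GSEA, weak enough per
  gene that it does not displace RNF43 from the top of the DE ranking.
* **AXIN2/RNF43 coupling**: CL2 samples carry a latent methylation level
  u ~ U(0,1); AXIN2 promoter probes gain `0.35·u` beta, AXIN2 expression
  loses `0.6·u`, and RNF43 receives an additional mean-zero term
  `−1.2·(u − mean(u))`, producing the anti-correlation without moving
  the planted mean log2FC.
* **Immune**: infiltration τ is 0.35 (APCmut+/normal), 0.42 (CL1 and
  fusion carriers), 0.55 (rest of CL2), log-normal noise SD 0.2; marker
  gene expression is signature × fractions; the M2-macrophage fraction
  is coupled to *realized* RSPO3 expression at target correlation 0.6.
* **Onset**: half of APCmut− forms a high-AP2M1 subgroup (+2 log2) whose
  ages are shifted −12 years against +12/2 in the complement, keeping
  the group mean at 61.4. Twelve years with SD 10 makes the effect
  reliably the strongest single-gene signal among ~2000 scanned genes —
  a pronounced but plausible early-onset subtype.
* **DMR decoys**: 12 hyper-methylated promoter regions, 3 hyper and 4
  hypo body regions (±0.10 beta in a random 60% of APCmut−,
  independent of cluster), giving the promoter-heavy hypermethylation
  pattern and realistic competition for the AXIN2 correlation ranking.
  Planted runs use 150 bp probe spacing; background probes are spaced
  1500–4000 bp so chance runs of significant probes rarely merge.

What the generator does **not** emulate: batch effects, copy-number
segment structure, probe-level array chemistry, realistic linkage between
mutations, censored or missing clinical data beyond the explicit
sentinels, and tumor purity variation. Passing recovery tests therefore
demonstrates that each algorithm detects the structure it is designed
for at realistic effect sizes and sample sizes — not that it is robust
to every artifact of real cohorts.

## Numerical and reproducibility choices

* One RNG seed in the pipeline config drives the permutation stages;
  the generator is fully deterministic given its own seed, and pipeline
  output files are byte-identical across reruns.
* All p-value floors use +1 pseudocounts (permutation tests) so no
  reported p is exactly 0; BH adjustment is the step-up procedure.
* Exact-test p-values are discrete and conservative; null-calibration
  tests therefore check that their empirical CDF never exceeds the
  uniform CDF (one-sided), rather than applying a two-sided
  goodness-of-fit test that discreteness would fail by construction.
* Degenerate inputs fail loudly: constant genes in z-scores, gene sets
  covering the whole ranking, empty groups in the logrank test, unsorted
  probe annotations. Empty *summary* groups are omitted with a warning
  instead, since partial cohorts are routine.
* Test problem sizes: unit tests run on a 24 + 60 + 6 sample cohort with
  400 genes and 1200 probes; the recovery suite runs the full default
  cohort once and shares it across tests; calibration uses 2000
  replicates (logrank), 2000 null genes (moderated t) and 100 decoy sets
  × 1000 permutations (GSEA).

## Known limitations

* The moderated t assumes a common variance model per gene and no
  covariate adjustment; mean–variance trends (voom-style weights) are
  not modeled.
* The DMR caller has no kernel smoothing and no per-region familywise
  error control beyond the probe-level BH threshold.
* NNLS deconvolution inherits the usual identifiability limits of linear
  mixing with correlated signatures; the bundled signature generator
  produces well-conditioned matrices, real signatures may not be.
* The logrank screen treats age at diagnosis as fully observed; if a
  cohort contains censoring-like structure (e.g. screening-detected
  cases), the no-censoring reduction is no longer exact.
* Pairwise mutual exclusivity only; k > 2 gene sets are out of scope.
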