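---
title: "Methylation subtyping across cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation subtyping across cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episubtype)
```

# The problem and the model

Bulk cortical DNA methylation in a case/control design mixes patients whose
epigenomes may differ systematically. The workflow in this package asks a
deliberately conservative question: do unsupervised clusters of disease
samples, found independently in several cohorts, describe the *same*
molecular subtypes? A cluster becomes a subtype only if it survives a
conjunction of checks — two clustering algorithms, two replication criteria
(probe-level correlation and sample-level latent-space projection), all
cohort pairs, both directions. Everything downstream (EWAS meta-analysis,
enrichment, colocalization, transcriptomic signatures) conditions on those
confirmed labels.

The modelling assumptions are, in order of appearance:

* **Residualization.** Covariate effects on methylation are linear and
  additive per probe; OLS residuals (intercept always included) remove
  them. Clustering operates on residuals, since technical and demographic
  structure otherwise dominates the between-sample distances. Raw-beta
  clustering remains possible by passing beta values directly.
* **Variance filtering.** A probe's usefulness for subtyping is its robust
  spread: the `quantile`-th percentile (default 0.90) of absolute
  deviations from the probe median. The published analyses report a
  retained-probe *count* but not the cutoff that produced it, so both an
  absolute cutoff (`min_score`) and a top-fraction mode are provided; the
  pipeline default keeps the top 10% of probes.
* **Clustering.** Ward.D2 on Euclidean distances and k-means
  (k-means++ seeding, `n_init = 25` restarts, best by within-cluster sum
  of squares) are both run; neither is trusted alone.
* **Latent projection.** Sparse PLS-DA in the Lê Cao formulation: per
  component the X-weight is the dominant singular vector of the deflated
  cross-covariance X'Y, soft-thresholded to exactly `keepX` nonzero
  entries and renormalized; X and Y are deflated by regression on the
  component score. Projection applies the stored centering/scaling and the
  rotation W(P'W)^-1, so training data reproduce training scores exactly —
  the property the hull test relies on.

# Choosing the number of clusters

The elbow criterion is formalized as the k maximizing the second difference
of the WCSS curve; the curve itself is returned for audit, ties break to
the smallest k, and a flat curve (best second difference below 5% of the
total scatter) is flagged `weak_elbow`. NMI between the two algorithms'
partitions (normalized by average entropy; min/max normalizations
selectable) measures their agreement.

Neither criterion suffices alone: on clean data both algorithms can agree
perfectly at several k (NMI ties at 1), and the second-difference rule
cannot nominate the smallest k in its range. `discover_subtypes()` therefore
uses the sequence: each algorithm's elbow proposes a candidate k over
`k_range` (default 1:6, so k = 2 is an interior candidate), and the
candidate with the highest inter-algorithm NMI wins, ties to the smallest.
The exported `elbow_select()` and `consensus_k()` keep their simple
single-criterion contracts.

Cluster labels are canonicalized by decreasing cluster size — names carry
no meaning, and deterministic naming replaces arbitrary relabelling.

# Replication and confirmation

Probe-level: per-cluster median beta profiles on the clustering probe set,
Pearson correlation, mutual-best one-to-one matching (a pair must be both
the row and column maximum, and exceed `min_r`, default 0). Sample-level:
replication samples are projected onto the first two latent components of
the discovery model; the convex hull of each discovery cluster is drawn
from its training scores ("connecting the outermost points"); boundary
points count as inside (exact point-in-polygon by half-plane tests with a
relative tolerance, not a grid approximation); a sample inside several
hulls counts for each. Each (replication cluster, discovery hull) cell is
tested with an upper-tail hypergeometric test — the one-sided Fisher test
— with population all projected replication samples; Bonferroni correction
is applied across the tested cells within each direction (the original
report is silent here; per-direction Bonferroni is the conservative
choice).

A confirmed subtype is a clique: one cluster per cohort, mutually matched
and hull-significant in every direction, under both clustering methods
(k-means labels aligned to hierarchical ones by exact maximum-trace
matching over label permutations, k ≤ 8). Clusters outside every clique
are Unassigned, and so are samples whose two algorithms disagree.

Degenerate inputs are handled explicitly: discovery clusters with fewer
than three distinct projected points are flagged and skipped; zero-variance
median profiles yield missing correlations rather than errors; if fewer
than 90% of model features are present in a replication cohort, projection
warns (it errors below that).

**Sparsity of the projection model.** The pipeline default is
`keepX = 50` per component on the ~500 clustering probes. Spreading the
weights over many probes dilutes them with noise dimensions, which
inflates the projected within-cluster spread of replication samples
relative to the training hulls and starves the overlap test; concentrated
weights on the strongest subtype CpGs keep the projected geometry
comparable across cohorts. `splsda_fit()` itself defaults to the published
scale (6 components × 2000 features), appropriate for full-size arrays.

# EWAS, empirical null, and meta-analysis

Each subtype is compared against healthy controls with the other disease
samples excluded — the reference-group convention matching the overall
case/control framing; subtype-vs-rest is available via `reference =
"rest"`. Surrogate variables are principal components of the
design-residualized matrix; their number is chosen by parallel analysis
(per-probe permutation of the input, residualized identically, keep
components exceeding every permuted leading singular value — a
deliberately conservative rule). This is a declared simplification of
iteratively-reweighted surrogate-variable analysis: deterministic,
orthogonal to the design by construction, and sufficient for the
batch-style hidden structure it is meant to absorb.

The empirical-null correction estimates bias μ and inflation σ of
z = effect/se with a three-component normal mixture fitted by EM
(median/MAD initialization). Two constraints make the estimator behave at
the boundaries: the signal components' means must flank the null mean by
at least two null SDs (otherwise they eat the shoulders of an already
calibrated null), and correction is applied only when σ̂ > 1.05 or
|μ̂| > 0.05 — the "if needed" rule, with ε exposed. The corrected scale is
z' = (z−μ̂)/σ̂, se' = σ̂·se, effect' = effect − μ̂·se. The Gibbs-sampler
implementation of the same mixture is deliberately replaced by EM:
deterministic and testable; stochastic equivalence is not claimed.

Meta-analysis: fixed-effect closed form, or REML random effects (the
default of the cited meta-analysis routine) by direct restricted-likelihood
maximization per probe (`optimize` on [0, 4·max(se², var)] with tolerance
1e-10, τ² = 0 taken when the boundary value is no worse); Q and I² are
reported, single-study probes pass through flagged. DMPs require
m·p < 0.05 strictly, m the number of meta-analyzed probes.

# Overlap statistics and colocalization

Overlap tests report the *conditional-MLE* odds ratio — the root of
E[A|ψ] = a under Fisher's noncentral hypergeometric model, solved by
bracketed root-finding on log ψ with exact log-space sums (relative
tolerance 1e-6) — plus the sample OR ad/bc and a flag when the two
disagree by more than 2%. At the boundary of the support the OR is 0 or
∞ by convention. The default universe for DMP-overlap tests is the
meta-analyzed probe set, exposed as a parameter since published background
sets are rarely printed.

Colocalization uses the Wakefield approximation per variant,
log ABF = ½log(1−r) + ½rZ² with r = W/(V+W) and prior effect variance
W = 0.15² (or sdY-scaled), and the standard five-hypothesis posterior
computed in log-sum-exp space with priors p1 = p2 = 1e-4, p12 = 1e-5 (the
conventional defaults; the source report does not state its priors).
Significance is PP.H3+PP.H4 > 0.90. Region inclusion requires at least one
cis-mQTL with p < 1e-5 (strict), but colocalization then uses the region's
full variant complement: filtering variants first would delete a distinct
GWAS peak and make the two-independent-signals hypothesis undetectable.

# Transcriptomic signatures

Bulk counts pass the low-expression rule (count < 10 in strictly more than
80% of samples drops a gene), TMM normalization and log2-CPM with a 0.5
prior count (the canonical recipe: 30% M-trim, 5% A-trim, reference
library closest to the upper-quartile mean). Differential expression is
per-gene OLS with method-of-moments empirical-Bayes variance shrinkage;
the prior df is estimable or fixed (0 gives the ordinary t, ∞ the pooled
t, with the total df capped at the pooled df). The three-cohort filter
selects genes with p < 0.05 in all cohorts, |log2FC| > log2(1.5) in at
least one, and identical sign everywhere — monotone in all thresholds.
Pseudobulk sums single-cell counts per sample and state (exact integer
identity); a state is analyzed only when every compared group averages at
least `min_cells = 10` cells and `min_depth = 1000` summed counts per
sample (the published thresholds are unstated; both are exposed). The
state-level selection keeps genes significant subtype-vs-subtype *and*
versus controls in at least one subtype, pooled and deduplicated across
states.

# Platform preservation

Co-methylation modules are detected by average-linkage clustering on
1 − |r| with a fixed cut height — a declared simplification of weighted
network module detection, justified because modules serve only as a
cross-platform robustness check. The module eigenprobe is the first PC of
the standardized module submatrix, sign-aligned to the module mean
profile. A cluster-associated module (ANOVA p < 0.05) is "preserved" on
the 450K subset when the subset-recomputed eigenprobe still separates the
clusters and the full- and subset-eigenprobes do not differ within any
cluster (paired t; the subset eigenprobe is sign/scale-aligned to the full
one first, since a PC is defined only up to sign).

# The synthetic cohorts: what they emulate, and what they do not

`sim_config()` defaults describe the designed-for conditions: three
cohorts of 150 disease + 75 control samples, 5000 CpGs, two shared
subtypes differing by Δβ = 0.1 at 5% of probes each (disjoint sets, random
direction), one additional cluster present only in cohort 1 (30% of its
disease samples), linear covariate effects (age, sex, neuronal proportion,
batch) on 30% of probes, Gaussian noise of SD 0.3 on the logit scale
(≈0.05–0.07 on the beta scale, the typical residual spread of cortical
arrays), and a 450K-like platform covering 60% of probes for the last
cohort. Methylation is simulated on the logit scale and inverse-logit
transformed, so beta stays in (0,1) while effects are exactly linear on
the modelling scale. Expression is negative-binomial (dispersion 0.2) with
two-fold planted changes; single-cell states include two deliberately
sparse ones that fall below pseudobulk inclusion thresholds; CpG panels
are nested across three specificity levels with one microglial panel
enriched at a planted odds ratio; association tracks use standardized-trait
standard errors 1/√(2n·maf(1−maf)) and a single-block exponential LD decay
around each causal variant.

Every generator draws from its own named RNG substream, so adding one
generator never changes another's output, and a seed fully determines
everything.

What the generator does *not* emulate: probe-type chemistry and
normalization artefacts, spatially correlated co-methylation beyond the
planted blocks, realistic LD panels, cell-type deconvolution error,
missing values, or dropout structure in single-cell counts. Passing tests
therefore demonstrate that the algorithms implement their contracts and
recover planted structure under realistic noise — not that real cortical
data contain two subtypes.

# Numerical notes

* Hypergeometric hull p-values are discrete; the null-calibration check
  uses the standard randomized ("fuzzy") p-value, uniform in
  [P(X>a), P(X≥a)], which is exactly Uniform(0,1) iff the claimed null
  distribution is correct. Raw discrete p-values cannot pass a literal KS
  test, for any correct implementation.
* The conditional-MLE OR at default tolerance differs from the classical
  exact-test printout by up to ~1% for extreme tables — the printed value
  solves the same score equation at a coarser tolerance on an inverted
  scale; both the high-precision root and the sample OR are reported.
* k-means restarts, label permutations and EM are all seed-deterministic;
  the sPLS-DA weight sign is fixed by making the largest-magnitude loading
  positive.
* Test and acceptance problem sizes are scaled to the package's own
  design conditions: 3×150 samples and 5000 probes for end-to-end
  recovery, 50,000 z-scores for empirical-null recovery, 200 replicates
  for calibration checks, 100 (tests) / 30 (acceptance script) replicates
  for the null-confirmation rate, 50 replicates per colocalization
  scenario.

# Known limitations

* The confirmation rule is a hard conjunction; power drops quickly below
  ~100 disease samples per cohort or Δβ ≲ 0.05 at 5% causal probes.
* Exact label alignment enumerates permutations and is limited to k ≤ 8.
* Surrogate-variable and empirical-null estimators are simplified,
  deterministic stand-ins for their iterative/stochastic namesakes and are
  validated on the structures the generator plants, not on all real-data
  pathologies.
* Colocalization assumes at most one causal variant per trait per region;
  multi-signal fine-mapping is out of scope.
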