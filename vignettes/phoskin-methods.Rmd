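---
title: "Methods: phosphoproteomic subtyping and INKA kinase-activity profiling"
author: "phoskin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphoproteomic subtyping and INKA kinase-activity profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`phoskin` implements a label-free phosphoproteomic cohort analysis for
tumor tissue: ingestion of MaxQuant-dialect quantification tables,
channel-specific normalization and record filtering, unsupervised subtype
discovery by consensus clustering, moderated differential statistics,
single-sample rank enrichment at the gene and phosphosite level,
integrative inferred kinase activity (INKA) scoring, and the association of
kinase activities with overall survival. A synthetic-cohort generator with
planted ground truth makes every stage testable without any external data.

This vignette documents the models, the tunable parameters with their
defaults and units, the numerical conventions, and the design decisions
taken where more than one reasonable choice existed.

# Data model

Two enrichment channels are carried through the analysis:

* **global pS/T** — immobilized-metal-affinity (IMAC) enrichment, dominated
  by phosphoserine/phosphothreonine; available for every sample;
* **pY** — phosphotyrosine immunoprecipitation; typically available for a
  subset of samples (the default synthetic cohort has 33 of 42).

A `SiteMatrix` couples site annotation (protein accession, 1-based residue
position, residue, a 15-mer flanking window 'X'-padded at protein ends,
localization probability, multiplicity, decoy/contaminant flags) with a
site-by-sample intensity matrix. The site key is
`(protein, position, multiplicity)`; gene symbols are annotation only, so
symbol collisions cannot merge distinct sites. MaxQuant writes intensity 0
for unobserved values, so zero and absent are both stored as missing
(`NA`); no imputation is performed anywhere in the package.

Spectral-count evidence is aggregated from the evidence table as the sum of
MS/MS counts per (modified peptide, sample), then projected onto sites:
each peptide contributes its counts to every (protein, position) it
carries.

# Preprocessing

* **Record exclusion** removes reverse-database hits, potential
  contaminants and all-missing rows, and reports counts per reason.
* **Class-I filter** keeps sites with localization probability >= 0.75
  (boundary inclusive; the threshold is a parameter).
* **Normalization** is channel-specific: the global pS/T channel is scaled
  per sample so that each sample's median observed site intensity equals
  the median of the per-sample medians (any fixed target differs only by a
  global constant; the median-of-medians keeps the data on its own scale);
  the pY channel is scaled by mean lysate spectral-count total over the
  sample's total.
* **Data presence (DP)** filtering keeps features observed in at least a
  fraction `dp_fraction` of samples (default 0.10; 1.0 gives the
  complete-case subset used for sample-sample correlation QC). The
  boundary is inclusive and filters nest: a stricter fraction always keeps
  a subset.
* **Variability selection** ranks features by the median absolute
  deviation, MAD = median(|x - median(x)|), computed on observed values
  only and without the usual 1.4826 consistency constant (only the ranking
  matters). The top `ceiling(top_fraction * n)` features are kept, ties
  broken by feature order so the selection is deterministic. MAD is
  computed after log2 transform; because MAD is shift-invariant per
  feature, a shared multiplicative factor before the log cannot change the
  selection.
* **log2 transform** precedes variance ranking, clustering and testing;
  intensity data are approximately log-normal and the fold-change gates
  are ratio-scale.

# Consensus subtyping

Subtypes are found by Monti-style resampling consensus. For each candidate
k and each of `n_resamples` (default 250) resamples, `subsample_fraction`
(default 0.8) of the samples are drawn without replacement and clustered on
z-scored features; the consensus entry M_k(i, j) is the fraction of
co-samplings in which i and j co-clustered. Final labels cut an
average-linkage tree of 1 - M_k at the chosen k, with cluster ids
renumbered by decreasing size.

Missing entries in the (DP-filtered, MAD-selected) clustering matrix are
filled with the feature's observed minimum *inside the clustering step
only* — a low-abundance fill consistent with intensity-dependent dropout —
and never persisted.

**Choice of k.** Let A(k) be the area under the empirical CDF of the
off-diagonal consensus entries and dA(k) its relative increase
(dA at the smallest k is A itself). k grows while dA(k) >= `delta_min` and
stops at the first failure. Two coupled design choices make this rule
discriminate:

* the **inner clusterer defaults to average-linkage hierarchical
  clustering**. When k exceeds the real structure, hierarchical cutting
  peels small outlier groups whose membership is unstable across
  resamples, so A(k) gains little. k-means (available via
  `inner = "kmeans"`) instead forces balanced, often *stable* splits of
  real clusters, which keeps inflating A(k) at every k and defeats any
  area-based stopping rule.
* `delta_min` defaults to **0.10**. Re-assigning a single sample between
  clusters moves about 2/n of all pairs, so the relative area gain has an
  irreducible churn floor of roughly 2/n (about 0.05 at n = 42) even for
  pure noise; a genuine cluster resolution gains 0.4 or more at these
  cohort sizes. The default sits between the two with margin on both
  sides. Both the full dA profile and an explicit `chosen_k` override are
  exposed, so the emergent k is always inspectable and overridable.

All resampling and inner clustering is driven by a single seed through a
counter-based per-step derivation, so results are exactly reproducible and
permuting the input samples permutes the consensus matrix accordingly on
well-separated data.

# Differential statistics

Group contrasts use an empirical-Bayes moderated test on log2 intensities,
computed on observed values only (a feature needs >= 2 observations per
group, otherwise it is reported untested). Per feature, the pooled variance
s2_g with d_g residual dof is shrunk toward a prior (d0, s0^2) fitted by
moment matching on log s2_g across features: the excess of var(log s2_g)
over its sampling contribution (trigamma terms) identifies d0, the mean
identifies s0^2. The posterior variance is
(d0 s0^2 + d_g s2_g) / (d0 + d_g) and the t (two groups) or F (three or
more) statistic gains d0 prior dof. `d0 = 0` recovers the classic unpaired
test exactly; `d0 = Inf` fully shrinks to s0^2; both are available as
overrides and exercised in the tests, as is agreement with an independent
established implementation of the same fit.

Significance gates are boundary-inclusive: BH-adjusted q <= 0.05 and
|log2 FC| >= 1 (fold change 2). For three-group screens the fold-change
gate uses the largest pairwise difference of group means. The fold change
is the difference of log2 group means (ratio of geometric means), not the
ratio of arithmetic means — the ratio scale is what a doubling gate means
on log data. The pre-ranked enrichment metric is
r = -log10(p) x sign(log2 FC), with sign(0) = 0 and p = 0 capped at the
machine minimum with a warning.

Mann-Whitney and Kruskal-Wallis wrappers are provided for abundance-style
comparisons (exact Mann-Whitney for <= 8 observations per group without
ties; normal approximation with tie correction otherwise).

# Single-sample enrichment

The enrichment score of a signature in one unit (a sample profile or a
pre-ranked list) is the ssGSEA-convention integrated difference between the
weighted in-set ECDF and the unweighted out-of-set ECDF after ranking all
keys by value, descending:

ES = sum_i [ P_in(i) - P_out(i) ],
P_in(i) = sum_{j <= i, j in S} |r_j|^alpha / sum_{j in S} |r_j|^alpha,
P_out(i) = #{j <= i, j not in S} / (N - |S|).

Defaults: alpha = 0.25 for intensity profiles; alpha = 1 when scoring the
signed -log10 p pre-ranked metric. At alpha = 0 the score is purely
rank-based (invariant under monotone transforms, odd under ranking
reversal), properties the tests verify. Conventions: a signature covering
every key scores 0 (empty complement); an all-tied profile scores 0 with a
warning; signatures whose intersection with the unit's observed keys falls
outside [5, 1000] are skipped for that unit. No permutation normalization
is applied by default, so scores are comparable across units for one
signature, not across signatures of very different sizes.

Site-level (PTM-SEA-style) scoring keys signatures by the 15-mer flanking
window, scored on normalized site intensities. Duplicate windows are
collapsed first, keeping the entry with the largest row-sum intensity;
deduplication commutes with scoring, which the tests check. Enrichment
scores are averaged arithmetically per cluster for group-level summaries.

# INKA kinase-activity scoring

For each kinase k and analysis unit u (a sample, or a group with evidence
summed across its samples), four evidence arms are built from site-level
spectral counts (intensities can be substituted):

* `c_kin` — counts on the kinase's own phosphosites, excluding
  activation-loop sites;
* `c_act` — counts on its flagged activation-loop sites (so the two
  kinase-centric arms never double count);
* `c_psp` — counts on substrate sites with a curated kinase-substrate
  edge;
* `c_nwk` — counts on substrate sites with a predicted edge scoring at
  least `nwk_min_score` (default 2.0, boundary inclusive) *and* no curated
  edge from the same kinase — each substrate site counts once, curated arm
  first.

The kinase-centric evidence K = c_kin + c_act and substrate-centric
evidence S = c_psp + c_nwk are integrated as the geometric mean,
I_k = sqrt(K x S), so activity requires support from both perspectives and
the score is equivariant under a global scaling of a unit's evidence
(ranks are scale-invariant). Kinases with K > 0 but S = 0 have no substrate
relations contributing evidence; they are excluded from the ranked profile
and reported in a separate kinase-centric-only list rather than silently
dropped. In cross-sample score matrices those kinases carry 0, consistent
with I_k = 0 whenever either arm is 0. Ranks sort by decreasing score with
alphabetical tie-breaks; `top_n()` slices the top 20 by default.

Group profiles pool evidence by summation, not averaging, so rare but
strong evidence is retained; the per-kinase data presence (DP%, the
percentage of the group's samples whose own score is positive) is
annotated to expose that sparsity. Differential kinase activity between
groups is tested by Mann-Whitney on per-sample scores with BH adjustment.

The integration formula is deliberately isolated in `inka_score()` so that
alternative integration schemes can be substituted without touching arm
construction.

# Survival association

Per-kinase Spearman correlation between per-sample INKA scores and overall
survival in months, with the usual exact/approximate p-value handling;
kinases observed in fewer than 3 samples are skipped and constant score
vectors are reported not-assessable. OS is correlated directly, without a
censoring adjustment; when censored samples enter, a caveat is attached to
the result. This is a deliberate simplification — censoring truncates
precisely the long-survival tail, so rank correlations against observed OS
are attenuated toward zero relative to correlations against the latent
event time; the synthetic-cohort recovery rates computed by the acceptance
script quantify that attenuation under the generator's conditions.

The short/long outcome split uses a bimodal cutoff: a Gaussian kernel
density (Silverman's rule-of-thumb bandwidth, 512-point grid) on OS; with
two or more modes the cutoff is the lowest density minimum between the two
largest modes, otherwise no cutoff is proposed and the caller may configure
one. Outcome groups (by default restricted to treatment-naive patients)
are long: OS > cutoff, short: OS <= cutoff. The extreme-group differential
contrast reuses the moderated test but gates on *unadjusted* p <= 0.05 with
|log2 FC| >= 1 — at three-versus-three sample sizes an FDR gate would be
near-vacuous, and the contrast is explicitly exploratory.

Kaplan-Meier curves and two-group log-rank tests wrap the standard
survival-analysis machinery; with no censoring the product-limit estimate
equals 1 - ECDF of the event times, a identity kept under test.

# The synthetic cohort generator

The generator produces a full cohort with planted truth so that recovery,
calibration and determinism are all measurable. Its defaults are the study
conditions of the package's tests and acceptance script, fixed once:

* **Cohort**: n = 42 samples, 3 subtypes (balanced assignment), pY channel
  absent in 9/42 samples.
* **Network**: 18 kinases (every third a tyrosine kinase), 12 substrate
  edges each over 800 pS/T + 150 pY sites, 35% predicted edges with scores
  Uniform(1, 6) (so a 2.0 score cutoff removes about a fifth), one
  self-site plus one activation-loop site per kinase.
* **Signal**: kinase activity a[k, s] = 20 + 3 x [k assigned to
  subtype(s)] + N(0, 1) on the log2-intensity scale; one designated
  hyperactive kinase (default KIN01) receives one extra shift of 3 in its
  subtype. The extra boost exists because every kinase is subtype-shifted
  — without it no kinase would be *uniquely* top-ranked, and rank-recovery
  would be undefined. Site log2 intensity is the mean activity of its
  incoming kinases (edge weight 1/indegree keeps sites on the activity
  scale) plus N(0, 0.8).
* **Missingness**: observation ~ Bernoulli(plogis(-10 + 0.6 x log2
  intensity)) — missing not at random, with ~50% dropout three log2 units
  below baseline and ~12% at baseline.
* **Spectral counts**: Poisson with mean min(50, 2^(log2I - 20)); the cap
  mirrors the saturation of spectral counting, and the unit scale keeps
  the cap above the operating range of subtype-shifted kinases so planted
  activity differences survive the count transform.
* **Localization**: ~90% class-I sites (probability drawn from
  Uniform(0.75, 1), else Uniform(0.05, 0.75)).
* **Clinical**: KRAS mutant frequency 0.952 and TP53 0.738 (the cohort
  frequencies 40/42 and 31/42), KRAS alleles at their typed frequencies,
  treatment-naive fraction 23/42, cellularity ~ round(N(40, 15)) clipped
  to [10, 70] percent.
* **Survival**: exponential with median 18 months at average risk and
  log-hazard 0.8 per unit standardized activity of the prognostic kinase
  (default KIN01); independent exponential censoring tuned to a ~25%
  marginal censoring fraction; times rounded to 0.1 month.

What the generator does *not* emulate: correlated peptide-level missingness
within proteins, batch structure or run-order drift, multiplicity > 1
site records, stromal/tumor compartment mixtures, or realistic flanking
sequence composition (windows are uniform random amino acids). Passing
recovery tests therefore demonstrates that the pipeline's statistics behave
as designed under a clean generative model — not that real cohorts of this
size will yield equally clean subtypes or kinase rankings.

# Determinism and problem sizes

One global seed fans out to per-stage seeds through a counter-based scheme,
so adding a stage never perturbs earlier stages' randomness, and a full
pipeline rerun with the same seed is byte-identical (hash-compared in the
tests). All randomized tests fix their seeds. The test suite and the
acceptance script run the cohort at its native n = 42 with 800 + 150 sites;
consensus clustering uses 100 resamples in tests (250 in the pipeline
default), recovery loops use 10-50 replicate cohorts and calibration loops
1000 null replicates — sizes chosen so the whole suite completes in a few
minutes on one CPU while keeping binomial noise on recovery rates near one
percentage point.

# Known limitations

* Multiplicity variants are kept as separate site keys; the right
  collapsing rule is data-dependent and none is applied.
* The OS correlation ignores censoring (see above); a proportional-hazards
  regression is deliberately out of scope.
* Enrichment scores are unnormalized across signatures; comparing scores
  between signatures of very different sizes needs the permutation
  normalization this package does not provide.
* The moderated-test prior assumes exchangeable variances across features;
  strong mean-variance trends would call for a trended prior, which is not
  implemented.
* Consensus clustering k selection is a heuristic on the consensus CDF
  area; the dA profile and the `chosen_k` override are exposed precisely
  because no automatic rule is reliable on weakly structured data.
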