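# phoskin

Phosphoproteomic subtyping and integrative kinase-activity profiling for
label-free tumor cohorts.

Mass-spectrometry phosphoproteomics reads out aberrant signaling directly:
thousands of phosphoserine/threonine (pS/T) and phosphotyrosine (pY) sites
quantified across tumors. `phoskin` is for computational biologists who
need to go from MaxQuant-dialect output tables ("Phospho (STY) Sites",
"modificationSpecificPeptides", "evidence") to biological results: molecular
subtypes, differential phosphorylation, signature enrichment, ranked kinase
activities, and their association with patient survival — with every step
reproducible from a single seed.

## What it computes

* **Ingestion & filtering** — MaxQuant-dialect TSV readers; removal of
  reverse hits, contaminants and signal-free rows; class-I localization
  filter (probability >= 0.75).
* **Normalization** — median-site scaling for the global pS/T (IMAC)
  channel; total-lysate spectral-count scaling for the pY IP channel.
* **Subtyping** — data-presence (10%) and MAD top-fraction (10%) feature
  selection, then Monti-style resampling consensus clustering with
  CDF-area-based selection of k.
* **Differential statistics** — empirical-Bayes moderated t/F on log2
  intensities (moment-matching variance prior), BH adjustment, gates
  q <= 0.05 and |log2 FC| >= 1; signed −log10 p rank metric;
  Mann–Whitney / Kruskal–Wallis helpers.
* **Enrichment** — single-sample rank enrichment (ssGSEA convention) for
  gene signatures and flanking-window-keyed phosphosite signatures
  (PTM-SEA style, duplicate windows collapsed by row-sum abundance), with
  per-cluster averaging.
* **INKA** — integrative inferred kinase activity. Per kinase and unit,
  kinase-centric evidence K (own sites + activation-loop sites) and
  substrate-centric evidence S (curated + score-filtered predicted
  substrate sites) are combined as

      INKA(k) = sqrt(K × S)

  so a kinase must be supported from both perspectives; per-sample and
  pooled group profiles, top-20 rankings, and Mann–Whitney group
  comparisons.
* **Survival** — per-kinase Spearman correlation of INKA scores with
  overall survival, kernel-density bimodal OS cutoff, short/long
  outcome-group contrasts, Kaplan–Meier and log-rank summaries.
* **Synthetic cohorts** — a generator with planted subtype structure,
  kinase-driven site intensities, intensity-dependent (MNAR) missingness,
  spectral counts, clinical covariates and survival, so the entire
  pipeline is testable offline with known truth.

## Worked example

```r
library(phoskin)

cohort <- simulate_cohort(sim_config(seed = 42))
counts <- site_spectral_counts(cohort$evidence, cohort$sites_global)
groups <- group_profile(counts, cohort$truth$network,
                        cohort$truth$subtype_labels, channel = "pST")
head(top_n(groups[["1"]], 5))
#>   kinase c_kin c_act c_psp c_nwk kin_evidence sub_evidence     score rank dp_pct
#> 1  KIN01   604   638  4267  3012         1242         7279 3006.7454    1    100
#> 2  KIN13   258   227  1532   572          485         2104 1010.1683    2    100
#> 3  KIN04   192   155  1104   681          347         1785  787.0165    3    100
#> 4  KIN16    83   127   781   424          210         1205  503.0408    4     93
#> 5  KIN10    91   117   908   180          208         1088  475.7142    5    100
```

KIN01 — the cohort's planted hyperactive kinase — tops the group-1 ranking:
its kinase-centric evidence (604 self-site + 638 activation-loop counts)
and substrate-centric evidence (4267 curated + 3012 predicted substrate
counts) combine to INKA = sqrt(1242 × 7279) ≈ 3007, detected in 100% of the
group's samples (`dp_pct`).

```r
smat  <- inka_score_matrix(inka_sample_profiles(counts, cohort$truth$network))
assoc <- spearman_survival(smat, cohort$clinical)
head(assoc, 3)
#>   kinase        rho           p n_used direction
#> 1  KIN07 -0.4915844 0.000945972     42      poor
#> 2  KIN01 -0.3802434 0.012992209     42      poor
#> 3  KIN04 -0.3508012 0.022740626     42      poor
```

Negative rho with small p flags kinases whose higher inferred activity
accompanies shorter overall survival ("poor" direction); KIN01 is the
cohort's planted prognostic kinase.

The full pipeline — simulate, write/read MaxQuant-dialect fixtures,
preprocess, subtype, test, enrich, score, associate — runs from one config:

```r
out <- run_all(pipeline_config(out_dir = "run1", seed = 11))
out$report$subtype$chosen_k   # 3 on the default synthetic cohort
```

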