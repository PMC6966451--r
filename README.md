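# tadprog

Links the three-dimensional organization of the genome to cancer
prognosis. The genome folds into topologically associating domains
(TADs) — megabase-scale regions whose regulatory elements interact mostly
internally — and somatic copy-number variants (CNVs) that recur inside
particular TADs can carry prognostic information even when they touch no
known cancer gene. `tadprog` is for computational biologists who want to
run, extend, or stress-test that analysis end-to-end:

1. **Consensus TAD map.** Per-tissue TAD maps (BED-like intervals) are
   integrated into one consensus segmentation. Tissues are weighted by
   their contribution to overall expression divergence (average-linkage
   clustering on 1 − Pearson *r*, equal-splits leaf weights). For 40-kb
   windows stepped by 1 kb, a conservation score
   `c_i = (1/L) Σ_j Σ_k w_k I_T(j,k)` (weighted fraction of window
   nucleotides inside a TAD) and a boundary score
   `b_i = Σ_k w_k I_B(i,k)` are computed; windows merge while the running
   mean conservation stays ≥ 0.5 and no window has boundary score ≥ 0.5.
   Runs ≥ 40 kb are consensus TADs; inter-TAD regions ≤ 400 kb are
   topological boundary regions (TBRs), longer ones disorganized
   chromatin.
2. **CNV enrichment.** Filtered CNV segments (1 kb < length ≤ 10 Mb,
   |segment mean| > 0.1, ≥ 10 probes) define a binary patient × TAD
   presence matrix (≥ 1 bp overlap). Each TAD's patient count is compared
   with counts for size-matched random genomic regions; empirical
   p-values are tie-inclusive fractions at α = 0.05.
3. **TAD-based survival models.** For eligible cohorts (≥ 100 patients,
   ≥ 10% deaths), K repeated 2/3–1/3 splits each fit a LASSO Cox model
   (5-fold CV, `lambda.min`), keep the top-ten |coefficient| features,
   and score the test third (Harrell's c-index). Run *i* is weighted
   `w_i = (1/K)·exp(ln2 · devCI_i / 0.1)` for `CI_i ≥ 0.5` (doubling per
   0.1 of c-index above the mean); each feature's aggregated weight `P_j`
   is the normalized-weight sum over runs selecting it. The top-ten `P_j`
   features enter a final Cox model pruned by backward elimination
   (Wald p ≤ 0.05, BH q-values reported), which stratifies patients at
   the median risk score (log-rank test) and can be applied frozen to an
   external cohort.
4. **TAD perturbation classes.** Normal consensus TADs are classified
   against a cancer consensus map: constitutive (reciprocal overlap
   ≥ 0.95), perturbed (either directional overlap ≤ 0.7), otherwise
   ambiguous; perturbed TADs subdivide into split (≥ 2 cancer TADs ≥ 95%
   inside) and fused (≥ 2 perturbed normal TADs ≥ 95% inside one cancer
   TAD). Scale-regions and reference-point meta-profiles summarize
   patient-level CNV coverage around TADs and TBRs.

A synthetic-cohort generator (`sim_config()`, `simulate_tad_maps()`,
`simulate_expression()`, `simulate_cnvs()`, `simulate_survival()`)
produces all inputs with known ground truth — jittered/split/fused tissue
maps, clade-structured counts, spiked per-TAD CNV recurrence,
proportional-hazards survival — so the whole pipeline is testable without
external data.

## Worked example

Simulate a 300-patient cohort on a 150-Mb genome with 30 CNV-enriched
TADs, three of which carry a true hazard ratio of 2, then run the
prognostic chain:

```r
library(tadprog)

cfg <- sim_config(seed = 42, n_patients = 300, cnv_mu = 7,
                  cancer_types = "SYN",
                  enriched_tads = seq(4, 120, by = 4)[1:30],
                  enrich_factor = 3, causal_tads = c(1, 10, 20),
                  log_hr = log(2), censor_frac = 0.25)
sim  <- simulate_tad_maps(cfg)
mw   <- rep(1 / length(sim$maps), length(sim$maps))
seg  <- build_consensus(window_scores(sim$maps, mw, cfg$chrom_sizes))
seg
#> consensus segmentation: 2 disorganized, 153 TAD, 130 TBR

cnvs <- filter_cnvs(simulate_cnvs(cfg, sim$base))
tads <- sim$base[cfg$enriched_tads, ]
m    <- overlap_matrix(cnvs, tads, patients = sprintf("SYN-P%03d", 1:300))
surv <- simulate_survival(cfg, m)
feat <- encode_features(m[surv$patient_id, ], surv$age, surv$sex,
                        median(surv$age))
runs <- run_repeated_models(feat, surv$time, surv$event, K = 100,
                            seed = 44, ages = surv$age)
runs
#> 100 completed LASSO Cox runs; median test c-index 0.606 (IQR 0.584-0.621)

agg <- aggregate_features(runs, universe = colnames(feat))
fm  <- fit_final_model(feat, surv$time, surv$event, head(agg$feature, 10))
fm
#> final Cox model on 300 patients, 5 prognostic feature(s):
#>                           coef    HZ        p        q flag
#> age_high                0.2867 1.332 3.71e-02 3.71e-02
#> chr1:3556000-4523000    0.4178 1.519 9.29e-03 1.55e-02
#> chr1:45795000-46476000  0.8544 2.350 1.16e-07 5.82e-07
#> chr1:55327000-56067000 -0.4252 0.654 1.91e-02 2.38e-02
#> chr2:30021000-30708000  0.5365 1.710 1.79e-03 4.47e-03

stratify_and_test(fm, feat, surv$time, surv$event)
#> risk stratification: 160 low / 140 high; log-rank p = 2.51e-11
```

The three simulated causal TADs (`chr1:3556000-4523000`,
`chr1:45795000-46476000`, `chr2:30021000-30708000`) are all retained with
hazard ratios near their generative value of 2, alongside the true age
effect; `chr1:55327000-56067000` is a post-selection false positive of
the kind the q-value flag is designed to expose (see the methods
vignette). The median test c-index of 0.61 falls in the [0.55, 0.8]
band that `reliability_flag()` marks as a usable model.

Enrichment testing against size-matched random regions, on a cohort with
a single TAD spiked to 3× background recurrence:

```r
cfg1  <- sim_config(seed = 61,
                    chrom_sizes = c(chr1 = 6e7, chr2 = 5e7, chr3 = 4e7),
                    n_patients = 100, cnv_mu = 7,
                    enriched_tads = 25L, enrich_factor = 3)
base  <- simulate_base_map(cfg1)
cnvs1 <- filter_cnvs(simulate_cnvs(cfg1, base))
er    <- enrichment_test(base[c(25, 10, 60), ], cnvs1, cfg1$chrom_sizes,
                         n_perm = 200, seed = 62)
#>                   tad_id observed expectation log2_fold p_enriched     call
#> 1 chr1:25648000-26884000       24        8.02     1.582      0.005 enriched
#> 2 chr1:10323000-11053000        9        6.36     0.501      0.145     none
#> 3   chr2:3481000-5082000        8        8.59    -0.103      0.660     none
```

The spiked TAD is recovered with a log2 fold-difference of 1.58
(log2 3 ≈ 1.585); unspiked TADs sit near zero and are not called.

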