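---
title: "Methods: consensus TAD maps, CNV enrichment, and TAD-based prognosis"
author: "tadprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus TAD maps, CNV enrichment, and TAD-based prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadprog)
```

# The analysis arc

Topologically associating domains (TADs) are megabase-scale regions of the
genome with preferential internal chromatin contacts. They are largely
conserved across tissues, and their disruption — boundary loss, splits,
fusions — can rewire enhancer-promoter contacts in cancer. `tadprog`
implements one coherent analysis built on that biology:

1. integrate per-tissue TAD maps into a single **consensus TAD map** of the
   genome, weighting tissues by their contribution to overall expression
   divergence;
2. test each consensus TAD for **enrichment or depletion of somatic copy
   number variants (CNVs)** across a patient cohort, against size-matched
   random genomic regions;
3. use CNV presence in the enriched TADs as binary features in **repeated
   LASSO Cox survival models**, aggregate the feature selections, fit a
   final proportional-hazards model, and stratify patients into risk
   groups;
4. **classify** each normal-genome TAD against a cancer-genome consensus
   map as constitutive, perturbed, split, or fused, and compute binned
   coverage meta-profiles around TADs and their boundary regions.

All coordinates are 0-based and half-open. Every step consumes and
produces plain data frames (plus small S3 wrappers), so each module can be
used on its own.

# Consensus TAD construction

## Tissue weights

Tissues are not independent samples: two lymphoblastoid lines agree about
TAD structure mostly because they are the same kind of cell. To keep
related tissues from dominating the consensus, each tissue receives a
weight derived from an expression dendrogram:

* counts are variance-stabilized with `log2(count / size_factor + 1)`
  using median-of-ratios size factors (the per-gene geometric mean across
  tissues as reference). This is a deliberately simple, fully specified
  monotone transform with the same variance-flattening intent as the
  model-based transforms used in differential-expression frameworks;
* the 2000 genes with the largest maximum absolute deviation from their
  median expression are kept (`select_variable_genes()`), ties broken by
  gene id;
* tissues are clustered with average linkage on `1 - Pearson r`
  (`build_dendrogram()`). Anti-correlated tissues give distances in
  (1, 2], which are used as-is; a constant expression profile is an error
  because its correlation is undefined;
* `leaf_weights()` attributes each edge of the tree equally to the leaves
  below it (the *equal-splits* rule): a leaf's raw score is
  `sum(length(e) / leaves_below(e))` along its root path, normalized to
  sum to one. Redundant tissues share, rather than double, the weight of
  their common branch. The rule is isolated behind one function so a
  different attribution (e.g. a Brownian-motion trajectory model) can be
  swapped in without touching anything downstream. Weights are invariant
  to uniform rescaling of all branch lengths, so the particular height
  convention of the clustering does not matter.

When a tissue contributed several TAD maps, `assign_map_weights()` splits
its weight equally among them and renormalizes the per-map weights to one.

## Windowed scores and merging

`window_scores()` slides 40-kb windows in 1-kb steps along each
chromosome (consecutive windows overlap by 97.5%). Per window it computes:

* a **conservation score** `c`: the weighted average over maps of the
  fraction of window nucleotides inside a TAD (in `[0, 1]`);
* a **boundary score** `b`: the summed weight of maps with at least one
  TAD boundary strictly inside the window.

A boundary coordinate `p` counts as inside window `[a, b)` only when
`a < p < b`. This strictness is load-bearing: windows flush against a
TAD's own ends do not see those ends as boundaries, which is what makes
the consensus of N identical maps reproduce the input boundaries exactly
on the step grid. Terminal windows are truncated at the chromosome end and
scored over their actual length, so chromosome tails are not lost.

`build_consensus()` merges windows greedily into maximal runs: a window
with `b >= 0.5` terminates the current run and belongs to none; otherwise
the window is appended as long as the running mean conservation stays at
or above 0.5. The phrase "average conservation over the merged region" is
ambiguous between a per-window and a per-run reading; both are
implemented (`average = "run"` is the default, `"window"` the
alternative) and they agree on clean tracks. One consequence of the run
average is that a run can extend through a low-conservation stretch if no
boundary wall stops it; run spans are clipped at the next run's start and
the minimum-size filter is re-applied until stable, so output regions
never overlap. Runs spanning at least 40 kb become consensus TADs; every
region between TADs (including chromosome-terminal stretches) is labeled
a topological boundary region (TBR) when at most 400 kb long and a
disorganized chromatin region otherwise. The output is a partition of
each chromosome.

`map_similarity()` quantifies agreement between two maps: for each TAD of
A, the largest fraction covered by a *single* TAD of B, median over A's
TADs. It is deliberately asymmetric.

# CNV enrichment

`filter_cnvs()` keeps segments longer than 1 kb and at most 10 Mb, with
absolute segment mean above 0.1 and at least 10 probes. `overlap_matrix()`
marks a patient as affected in a TAD when any of their CNVs overlaps it by
at least one base (abutting half-open intervals share none). Gains and
losses are pooled by default, with a sign-stratified variant behind
`by_sign = TRUE`.

`enrichment_test()` draws, for each TAD, `n_perm` random regions of the
same length, placed uniformly over all valid genome positions: a
chromosome is chosen with probability proportional to its number of valid
start positions, the start uniformly within it, so regions never cross
chromosome ends. Empirical p-values are plain tie-inclusive fractions —
`p_enriched = mean(null >= observed)`, `p_depleted = mean(null <=
observed)` — so `p_enriched + p_depleted >= 1` always; a `plus_one` flag
gives the pseudo-count variant. Calls are made at `alpha = 0.05`. No
mappability masking is applied by default; a BED exclusion mask is
accepted and enforced by rejection sampling. Per-cancer-type and pooled
testing are the same operation applied to different patient subsets
(`sample_cohort()` draws seeded fixed-size cohorts per type).

The log2 fold-difference `log2(observed / mean(null))` is a ratio of a
binomial count to a well-estimated expectation; its sampling noise scales
as `1/sqrt(observed)`. It is therefore a pooled-cohort statistic: at a
few hundred patients the estimate is stable, while for a 100-patient
single-type cohort with typical counts near 10 the noise floor alone
exceeds 0.2 in log2. The tests evaluate fold concentration at
pooled-cohort scale for this reason.

# Survival modeling

Cohorts enter the analysis when, after removing patients with no filtered
CNVs, they keep at least 100 patients with at least 10% deaths
(`eligible_cohorts()`). Features are binary: CNV presence per enriched
TAD, `age_high` (age strictly above the training-set median), and `sex`
(1 = female). Constant columns are dropped with a warning.

`run_repeated_models()` repeats K times: a 2/3-1/3 train/test split; an
L1-penalized Cox fit on the training set with the penalty chosen by
5-fold cross-validation at minimum partial-likelihood deviance
(`lambda.min`); the ten features with the largest absolute coefficients
kept; and the held-out third scored with exactly those coefficients to
give a test concordance index (Harrell's C; tied scores count one half).
If cross-validation fails to converge, features are ranked by their order
of entry into the regularization path instead. Runs whose training split
lacks events are recorded as failed and excluded; K in the aggregation is
the number of completed runs. All randomness flows from one master seed
through a vector of per-run seeds drawn once, so individual runs are
reproducible regardless of K.

The operation takes a fixed feature table. Pipelines that want the
enrichment step recomputed inside each training split — the fully nested
variant — can pass a `refit_features` callback that maps a training index
to a replacement feature matrix; the default keeps the features fixed,
which is the tractable desk-scale choice, and `ages` re-binarizes the age
column against each run's training median either way.

Run-level results are combined by `aggregate_features()`: run `i` gets
raw weight `w_i = (1/K) * exp(ln(2) * devCI_i / 0.1)` when `CI_i >= 0.5`
and zero otherwise, where `devCI_i` is the run's deviation from the mean
c-index. The weight doubles for every 0.1 of c-index above the mean —
an exponential tilt toward the splits that actually predicted the
held-out patients. Weights are normalized to sum to one and each
feature's aggregated weight `P_j` is the summed weight of the runs
selecting it, so `P_j = 1` means "selected whenever the run was worth
anything". The ten features with the highest `P_j` seed the final model.

`fit_final_model()` fits an unpenalized Cox model and performs backward
elimination on Wald p-values until all remaining features satisfy
`p <= 0.05`; exact duplicate columns are resolved by keeping the
alphabetically first. Benjamini-Hochberg q-values are reported and
features with `q > 0.05` are flagged, but retention is governed by the
raw p-values. Because the candidates were already selected on the same
cohort, these p-values are post-selection quantities: a small number of
spurious features (about one in our synthetic replicates) survives
elimination, which is precisely what the q-value flag is there to
expose. `reliability_flag()` marks a cohort's model reliable when the
median test c-index over runs falls in [0.55, 0.8] — above chance but
short of too-good-to-be-true.

`stratify_and_test()` computes risk scores (`sum(coef * feature)`),
splits at the median (scores at or below the median are low risk — ties
go to low by explicit convention), and compares groups with Kaplan-Meier
curves and a log-rank test. If all scores are identical, stratification
is refused rather than fabricating groups. `evaluate_external()` applies
the frozen coefficients to an independent cohort and reports its
concordance; it never refits.

# Normal-vs-cancer TAD classification

`classify_tads()` compares two consensus maps. For each normal TAD,
`f_N` is the largest fraction covered by a single cancer TAD; for that
cancer TAD, `f_C` is the largest fraction covered by a single normal TAD,
and the pair is *reciprocal* when that normal TAD is the original one.
Constitutive requires reciprocity with both fractions at least 0.95;
perturbed requires either fraction at most 0.7 (a TAD with no cancer
partner is perturbed with zero fractions); everything else is ambiguous
and stays ambiguous — the class is a deliberate safety buffer, never
folded into the other two. Lowering the constitutive threshold can only
add constitutive TADs, and tightening the perturbed bound can only remove
perturbed ones; the tests assert both directions on jittered synthetic
maps.

`detect_split_fused()` refines the perturbed class: a normal TAD is
*split* when two or more cancer TADs each lie at least 95% of their own
length inside it, and a group of normal TADs is *fused* when each lies at
least 95% inside one covering cancer TAD. Fused groups are connected
components keyed by the covering cancer TAD, and all members must
themselves be perturbed (the strict reading); the two subsets are
disjoint by construction.

`scaled_profile()` and `reference_point_profile()` reimplement the two
standard meta-profile geometries: bodies linearly rescaled to 2 Mb with
1-Mb literal flanks in 10-kb bins (median aggregation across regions by
default, mean behind a flag), and fixed 5-kb bins over ±200 kb around
region centers with missing data as zero. For CNV signals the coverage
counts distinct patients per base (each patient's segments are merged
first), matching the convention of patient-recurrence tracks.

# The synthetic cohort generator

The generators exist so that every stage above can be tested against
known ground truth without any external download, and their defaults *are*
the study conditions of the tests:

* **Genome and TADs**: three chromosomes totalling 150 Mb; TAD sizes
  log-normal with median 1 Mb (sdlog 0.35, about 0.5–2 Mb), separated by
  log-normal gaps with median 80 kb, all on a 1-kb grid. This yields
  ~125 TADs, enough for the 150-TAD calibration runs with a fourth
  chromosome added.
* **Tissue maps**: each tissue jitters every boundary with Gaussian noise
  (default sd 20 kb, resampled/repaired if an interval would invert),
  splits a TAD with probability 0.05 and fuses an adjacent pair with
  probability 0.05. Tissues in a clade share half of the jitter variance
  and of the split/fusion draws (`clade_share = 0.5`), so related tissues
  get related maps.
* **Expression**: negative-binomial counts whose log-means carry a shared
  clade effect, so correlation clustering recovers the generating clades.
* **CNVs**: per patient a negative-binomial count (default mean 30,
  dispersion 2 — mid-range for the 3–280 per-patient medians seen across
  cancer types; the enrichment-calibration tests use mean 7, which gives
  the 0.1 per-TAD background recurrence those tests specify) of uniformly
  placed segments with log-uniform lengths between 1 kb and 10 Mb.
  Segment means come from a two-component mixture straddling ±0.1 and
  probe counts scale with length, so the CNV filters genuinely remove
  rows. Enrichment is spiked by *extra placements*: patients not already
  hitting the target TAD receive one CNV constrained to overlap it, with
  attributes drawn conditional on passing the filters, until post-filter
  recurrence reaches `factor ×` the TAD's own background (capped at
  0.95). Spiking never reweights existing segments, so kept-CNV length
  distributions are identical between spiked and background TADs and
  recurrence is the only signal.
* **Survival**: exponential baseline hazard (half-life 1000 days) times
  `exp(lp)` with the linear predictor summing causal TAD features
  (default log HR = ln 2), an age effect (log 1.5) and an optional sex
  effect. With an exponential baseline the Cox coefficients equal the
  generative log hazard ratios exactly, which keeps recovery assertions
  sharp. Censoring is uniform on `(0, c_max)` with `c_max` calibrated by
  root-finding so the expected censored fraction hits the target
  (default 25%).

What the generator does **not** emulate: real per-cancer-type CNV
spectra, germline events, mappability structure, batch effects between
Hi-C studies, or nested sub-TAD organization. Passing tests therefore
demonstrate that the algorithms do what they claim under the stated
statistical structure — not that the biological conclusions transfer to
any particular real cohort.

# Numerical choices and degenerate inputs

* Windows start at position 0 per chromosome; partial terminal windows
  keep their actual length.
* Similarity, classification, and aggregation ties break
  deterministically (leftmost partner, alphabetical feature name).
* Empty TAD map on the query side of `map_similarity()` is an error (the
  median is undefined), while an empty subject map scores 0.
* `enrichment_test()` errors when a TAD is longer than every chromosome;
  log2 fold is `-Inf` for zero observed counts and is reported as-is.
* A training split without events marks that run failed rather than
  aborting the repetition loop.
* Collinear duplicate features are dropped by name before the final Cox
  fit; residual `NA` coefficients are dropped iteratively.
* All generators are deterministic functions of `(config, seed)`; module
  seeds are offsets of the config seed so the map, expression, CNV, and
  survival draws are independent but jointly reproducible.

# Problem sizes

The shipped tests run the full arc at desk scale, chosen so the suite
stays fast while every statistical claim keeps a real margin: toy genomes
of 0.4–1 Mb for per-nucleotide oracle comparisons; 150 TADs × 100
patients × 200 permutations for calibration; 50 seeded cohorts at 400
patients for fold concentration; and 20 replicates of the full prognostic
chain (300 patients, 30 enriched TADs, 3 causal at HR 2, 25% censoring,
K = 100 repeated splits) for recovery and stratification. The same code
paths scale to cohort sizes like the real application's (thousands of
patients, K = 1000) by changing arguments only.
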