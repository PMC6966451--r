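mk_cnv <- function(patient, chrom, start, end, mean_ = 0.5, probes = 50,
                   type = "SIM") {
  data.frame(patient_id = patient, cancer_type = type, chrom = chrom,
             start = start, end = end, num_probes = probes,
             segment_mean = mean_, sign = ifelse(mean_ > 0, "gain", "loss"),
             stringsAsFactors = FALSE)
}

test_that("CNV filters enforce the length, segment-mean, and probe rules", {
  segs <- rbind(
    mk_cnv("P1", "chr1", 0, 500),                       # 500 bp: too short
    mk_cnv("P1", "chr1", 0, 1000),                      # exactly 1 kb: excluded
    mk_cnv("P1", "chr1", 0, 1001),                      # just over 1 kb: kept
    mk_cnv("P1", "chr1", 0, 1e7),                       # exactly 10 Mb: kept
    mk_cnv("P1", "chr1", 0, 1e7 + 1),                   # over 10 Mb: excluded
    mk_cnv("P2", "chr1", 0, 2e6, mean_ = 0.05),         # |mean| <= 0.1: excluded
    mk_cnv("P2", "chr1", 0, 2e6, mean_ = 0.1),          # exactly 0.1: excluded
    mk_cnv("P2", "chr1", 0, 2e6, mean_ = -0.3, probes = 15),  # kept
    mk_cnv("P3", "chr1", 0, 2e6, probes = 9),           # too few probes
    mk_cnv("P3", "chr1", 0, 2e6, probes = 10)           # kept
  )
  kept <- filter_cnvs(segs)
  expect_equal(kept$end - kept$start, c(1001, 1e7, 2e6, 2e6))
  expect_equal(kept$patient_id, c("P1", "P1", "P2", "P3"))
})

test_that("cohort sampling is seeded, uniform, and excludes small types", {
  pats <- data.frame(patient_id = sprintf("P%03d", 1:250),
                     cancer_type = rep(c("AA", "BB", "CC"), c(100, 120, 30)))
  expect_warning(s1 <- sample_cohort(pats, n = 100, seed = 4), "CC")
  expect_equal(nrow(s1), 200)
  expect_equal(sum(s1$cancer_type == "AA"), 100)   # exactly-100 type fully kept
  expect_setequal(s1$patient_id[s1$cancer_type == "AA"],
                  pats$patient_id[pats$cancer_type == "AA"])
  s2 <- suppressWarnings(sample_cohort(pats, n = 100, seed = 4))
  expect_identical(s1, s2)                          # same seed, same subset
  s3 <- suppressWarnings(sample_cohort(pats, n = 100, seed = 5))
  expect_false(identical(s1$patient_id, s3$patient_id))
})

test_that("patient-by-TAD matrix uses >= 1 bp overlap on half-open intervals", {
  tads <- data.frame(chrom = "chr1", start = c(0, 2000, 4000),
                     end = c(1000, 3000, 5000))
  cnvs <- rbind(
    mk_cnv("P1", "chr1", 1000, 2000),   # abuts TAD1 and overlaps TAD2? no:
                                        # [1000,2000) touches neither 0-1000 nor 2000-3000
    mk_cnv("P2", "chr1", 500, 4500),    # spans all three TADs
    mk_cnv("P3", "chr1", 2999, 3000)    # 1 bp inside TAD2
  )
  m <- overlap_matrix(cnvs, tads)
  expect_equal(unname(m["P1", ]), c(0L, 0L, 0L))
  expect_equal(unname(m["P2", ]), c(1L, 1L, 1L))
  expect_equal(unname(m["P3", ]), c(0L, 1L, 0L))
  # patients without CNVs are excluded from the rows, with a message
  expect_message(m2 <- overlap_matrix(cnvs, tads, patients = c("P1", "P2", "P3", "P9")),
                 "1 patient")
  expect_equal(rownames(m2), c("P1", "P2", "P3"))
  # sign-stratified variant
  ms <- overlap_matrix(rbind(mk_cnv("P1", "chr1", 0, 100, mean_ = 0.5),
                             mk_cnv("P1", "chr1", 2000, 2100, mean_ = -0.5)),
                       tads, by_sign = TRUE)
  expect_equal(unname(ms$gain["P1", ]), c(1L, 0L, 0L))
  expect_equal(unname(ms$loss["P1", ]), c(0L, 1L, 0L))
})

test_that("overlap counting matches the brute-force pairwise oracle", {
  set.seed(11)
  cfg <- sim_config(seed = 31, chrom_sizes = c(chr1 = 1e7, chr2 = 8e6),
                    n_patients = 20, cnv_mu = 10)
  base <- simulate_base_map(cfg)
  cnvs <- filter_cnvs(simulate_cnvs(cfg, base))
  m <- overlap_matrix(cnvs, base)
  for (p in rownames(m)) {
    pc <- cnvs[cnvs$patient_id == p, ]
    manual <- as.integer(vapply(seq_len(nrow(base)), function(t) {
      any(pc$chrom == base$chrom[t] & pc$start < base$end[t] &
            pc$end > base$start[t])
    }, TRUE))
    expect_equal(unname(m[p, ]), manual)
  }
  # per-CNV TAD-overlap counts against the O(n*m) oracle
  counts <- oracle_cnv_tad_counts(cnvs, base)
  via_matrix <- colSums(m)
  expect_equal(unname(via_matrix),
               oracle_patient_counts(base, cnvs))
  expect_true(all(counts >= 0))
})

test_that("enrichment p-values behave at the degenerate extremes", {
  sizes <- c(chr1 = 1e6)
  tads <- data.frame(chrom = "chr1", start = c(1e5, 5e5), end = c(2e5, 6e5))
  # every patient's CNV tiles the whole genome: observed = null everywhere
  cnvs <- rbind(mk_cnv("P1", "chr1", 0, 1e6), mk_cnv("P2", "chr1", 0, 1e6))
  res <- enrichment_test(tads, cnvs, sizes, n_perm = 50, seed = 1)
  expect_equal(res$p_enriched, c(1, 1))
  expect_equal(res$p_depleted, c(1, 1))
  expect_equal(res$call, c("none", "none"))
  expect_equal(res$log2_fold, c(0, 0))
  # both p-values include ties, so they always sum to at least 1
  expect_true(all(res$p_enriched + res$p_depleted >= 1))
  # a TAD longer than every chromosome cannot be permuted
  expect_error(enrichment_test(data.frame(chrom = "chr1", start = 0, end = 2e6),
                               cnvs, sizes, n_perm = 10),
               "exceeds")
})

test_that("an observation above all null counts is called enriched at p = 0", {
  sizes <- c(chr1 = 5e7)
  tad <- data.frame(chrom = "chr1", start = 1e6, end = 2e6)
  # 30 patients all hit the TAD; elsewhere the genome is CNV-free
  cnvs <- do.call(rbind, lapply(1:30, function(i) {
    mk_cnv(sprintf("P%02d", i), "chr1", 1.4e6, 1.6e6)
  }))
  # masking the TAD keeps random regions off the hotspot, so every null
  # count is strictly below the observation
  res <- enrichment_test(tad, cnvs, sizes, n_perm = 100, seed = 2, mask = tad)
  expect_equal(res$observed, 30)
  expect_equal(res$p_enriched, 0)
  expect_equal(res$call, "enriched")
  # plus-one correction keeps the p-value strictly positive
  res1 <- enrichment_test(tad, cnvs, sizes, n_perm = 100, seed = 2,
                          plus_one = TRUE, mask = tad)
  expect_equal(res1$p_enriched, 1 / 101)
})

test_that("a CNV-free TAD in a dense genome is called depleted", {
  sizes <- c(chr1 = 4e7)
  tad_free <- c(2e7, 2.05e7)    # 0.5 Mb hole
  cnvs <- do.call(rbind, lapply(1:40, function(i) {
    set.seed(100 + i)
    s <- sort(sample(seq(0, 3.95e7, by = 5e4), 60))
    keep <- s + 5e4 <= tad_free[1] | s >= tad_free[2]
    mk_cnv(sprintf("P%02d", i), "chr1", s[keep], s[keep] + 5e4)
  }))
  tads <- data.frame(chrom = "chr1", start = tad_free[1], end = tad_free[2])
  res <- enrichment_test(tads, cnvs, sizes, n_perm = 200, seed = 42)
  expect_equal(res$observed, 0)
  expect_gt(res$expectation, 0)
  expect_equal(res$call, "depleted")
})

test_that("unspiked fold-differences concentrate near zero in log2", {
  # one ordinary TAD, 50 cohort/permutation seeds, pooled-cohort scale
  # (fold-differences are a pooled-cohort statistic; at a few hundred
  # patients the log2 ratio of observed to expected counts is stable)
  lf <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = 1000 + s, n_patients = 400, cnv_mu = 30)
    base <- simulate_base_map(cfg)
    cnvs <- filter_cnvs(simulate_cnvs(cfg, base))
    enrichment_test(base[20, ], cnvs, cfg$chrom_sizes, n_perm = 200,
                    seed = 2000 + s)$log2_fold
  }, 0)
  expect_lt(mean(abs(lf)), 0.2)
})

test_that("gene annotation assigns by >= 1 bp overlap, straddlers to both", {
  tads <- data.frame(chrom = "chr1", start = c(0, 2000), end = c(1000, 3000))
  genes <- data.frame(chrom = "chr1", start = c(100, 900, 1200),
                      end = c(200, 2200, 1800),
                      name = c("inside", "straddle", "in_tbr"))
  ann <- annotate_genes(tads, genes)
  expect_setequal(ann[[1]], c("inside", "straddle"))
  expect_equal(ann[[2]], "straddle")
  expect_false("in_tbr" %in% unlist(ann))
})
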