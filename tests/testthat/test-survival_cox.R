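test_that("cohort eligibility applies the size and lethality thresholds", {
  mk_clin <- function(type, n, deaths) {
    data.frame(patient_id = sprintf("%s-%03d", type, 1:n), cancer_type = type,
               time = rep(100, n), event = rep(c(1, 0), c(deaths, n - deaths)),
               age = 60, sex = "female")
  }
  clin <- rbind(mk_clin("A", 120, 15),   # 12.5% lethal, n >= 100: in
               mk_clin("B", 99, 50),     # n < 100: out
               mk_clin("C", 200, 10),    # 5% lethal: out
               mk_clin("D", 100, 10))    # exactly 10%, exactly 100: in
  el <- eligible_cohorts(clin)
  expect_equal(el$eligible[match(c("A", "B", "C", "D"), el$cancer_type)],
               c(TRUE, FALSE, FALSE, TRUE))
  # patients with no CNVs are excluded before thresholding
  el2 <- eligible_cohorts(clin, patients_with_cnvs = clin$patient_id[1:110])
  expect_equal(el2$n[el2$cancer_type == "A"], 110)
  expect_false("B" %in% el2$cancer_type[el2$eligible])
})

test_that("feature encoding binarizes age against the training median and drops constants", {
  m <- matrix(c(1, 0, 1, 0), 4, 1, dimnames = list(NULL, "tadX"))
  expect_warning(
    x <- encode_features(m, age = c(70, 65, 60, 80), sex = rep("female", 4),
                         train_median_age = 65),
    "sex")
  expect_equal(unname(x[, "age_high"]), c(1L, 0L, 0L, 1L))  # age == median -> 0
  expect_false("sex" %in% colnames(x))
  x2 <- encode_features(m, age = c(70, 65, 60, 80),
                        sex = c("female", "male", "male", "female"),
                        train_median_age = 65)
  expect_equal(unname(x2[, "sex"]), c(1L, 0L, 0L, 1L))
})

test_that("concordance matches exhaustive pair enumeration, including ties and censoring", {
  # perfect reverse ranking of uncensored times
  t <- c(5, 3, 9, 1, 7)
  expect_equal(concordance_index(-t, t, rep(1, 5)), 1)
  expect_equal(concordance_index(t, t, rep(1, 5)), 0)
  # random fixtures with tied scores and censoring vs the oracle
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    time <- rexp(n)                       # continuous: no tied times
    event <- rbinom(n, 1, 0.7)
    score <- sample(1:5, n, replace = TRUE)   # heavy score ties
    expect_equal(concordance_index(score, time, event),
                 oracle_cindex(score, time, event), tolerance = 1e-12)
  }
  expect_error(concordance_index(c(1, 2), c(5, 5), c(0, 0)), "comparable")
})

test_that("repeated LASSO Cox runs are deterministic and find a dominant feature", {
  set.seed(3)
  n <- 90
  x <- cbind(driver = rep(c(1, 0), each = n / 2),
             matrix(rbinom(n * 5, 1, 0.3), n, 5,
                    dimnames = list(NULL, sprintf("noise%d", 1:5))))
  # carriers die first, in a clean gradient; no censoring
  time <- ifelse(x[, "driver"] == 1, runif(n, 0, 50), runif(n, 100, 200))
  runs <- run_repeated_models(x, time, rep(1, n), K = 3, seed = 9)
  expect_length(runs, 3)
  sel <- lapply(runs, function(r) names(r$selected))
  expect_true(all(vapply(sel, function(s) "driver" %in% s, TRUE)))
  # binary risk scores tie within groups, capping Harrell's C below 1;
  # between-group pairs are all concordant
  expect_true(all(vapply(runs, `[[`, 0, "ci") > 0.7))
  runs2 <- run_repeated_models(x, time, rep(1, n), K = 3, seed = 9)
  expect_equal(runs, runs2)
  runs3 <- run_repeated_models(x, time, rep(1, n), K = 3, seed = 10)
  expect_false(identical(runs, runs3))
})

test_that("pure-noise features give chance-level mean concordance", {
  set.seed(17)
  n <- 120
  x <- matrix(rbinom(n * 8, 1, 0.3), n, 8,
              dimnames = list(NULL, sprintf("n%d", 1:8)))
  time <- rexp(n)
  runs <- run_repeated_models(x, time, rep(1, n), K = 50, seed = 2)
  ci <- vapply(runs, `[[`, 0, "ci")
  expect_lt(abs(mean(ci) - 0.5), 0.05)
})

test_that("aggregation reproduces the weighting scheme exactly", {
  # single run: devCI = 0, weight 1, selected feature gets P = 1
  r1 <- mk_runs(0.6, list(c("A", "B")))
  a1 <- aggregate_features(r1)
  expect_equal(a1$P, c(1, 1))
  # a run below 0.5 contributes nothing regardless of selections
  r2 <- mk_runs(c(0.62, 0.45), list("A", c("A", "B")))
  a2 <- aggregate_features(r2)
  expect_equal(a2$P[a2$feature == "A"], 1)
  expect_equal(a2$P[a2$feature == "B"], 0)
  # K = 2, CI 0.7/0.5: raw weights 1 and 0.25 -> normalized 0.8/0.2
  r3 <- mk_runs(c(0.7, 0.5), list(c("A", "B"), "B"))
  a3 <- aggregate_features(r3)
  expect_equal(attr(a3, "weights"), c(0.8, 0.2))
  expect_equal(a3$P[a3$feature == "A"], 0.8)
  expect_equal(a3$P[a3$feature == "B"], 1)
  # weight doubles per 0.1 of c-index above the mean (exact)
  r4 <- mk_runs(c(0.65, 0.75), list("A", "A"))
  w4 <- attr(aggregate_features(r4), "weights")
  expect_equal(w4[2] / w4[1], 2)
  expect_error(aggregate_features(mk_runs(c(0.4, 0.45), list("A", "B"))),
               "no informative runs")
})

test_that("aggregated weights are monotone in c-index and bounded in [0, 1]", {
  set.seed(8)
  ci <- round(runif(20, 0.5, 0.9), 3)
  r <- mk_runs(ci, as.list(sample(LETTERS[1:6], 20, replace = TRUE)))
  a <- aggregate_features(r)
  expect_true(all(a$P >= 0 & a$P <= 1))
  w <- attr(a, "weights")
  expect_equal(sum(w), 1)
  expect_true(all(diff(w[order(ci)]) >= 0))      # strictly increasing in CI
  # P = 1 iff selected in every positively weighted run
  r_all <- mk_runs(c(0.6, 0.7, 0.8), list(c("Z", "Q"), "Z", c("Z")))
  expect_equal(aggregate_features(r_all)$P[1], 1)   # Z ranked first with P = 1
})

test_that("the final Cox model recovers a known hazard ratio and eliminates noise", {
  set.seed(12)
  n <- 300
  x <- cbind(causal = rbinom(n, 1, 0.5),
             noise1 = rbinom(n, 1, 0.3), noise2 = rbinom(n, 1, 0.3))
  lp <- log(2) * x[, "causal"]
  time <- rexp(n, rate = 0.01 * exp(lp))
  fm <- fit_final_model(x, time, rep(1, n), colnames(x))
  expect_true("causal" %in% fm$features)
  expect_gt(fm$hazard_ratio[["causal"]], 1.5)
  expect_lt(fm$hazard_ratio[["causal"]], 2.7)
  expect_true(all(fm$p <= 0.05))
  expect_equal(fm$q, p.adjust(fm$p, "BH"))
  # collinear duplicate resolved deterministically by name
  x2 <- cbind(x, causal2 = x[, "causal"])
  expect_warning(fm2 <- fit_final_model(x2, time, rep(1, n), colnames(x2)),
                 "causal2")
  expect_false("causal2" %in% fm2$features)
  # pure noise: the model usually empties, and empties cleanly
  set.seed(30)
  empties <- vapply(1:10, function(i) {
    xn <- matrix(rbinom(150 * 3, 1, 0.4), 150, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
    fit_final_model(xn, rexp(150), rep(1, 150), colnames(xn))$empty
  }, TRUE)
  expect_gt(mean(empties), 0.5)
})

test_that("median-split stratification separates risk groups and refuses degenerate input", {
  set.seed(14)
  n <- 200
  x <- cbind(f = rbinom(n, 1, 0.5))
  time <- rexp(n, 0.01 * exp(1.5 * x[, "f"]))
  fm <- fit_final_model(x, time, rep(1, n), "f")
  st <- stratify_and_test(fm, x, time, rep(1, n))
  expect_lt(st$p_value, 0.05)
  expect_lt(median(time[st$group == "high"]), median(time[st$group == "low"]))
  expect_equal(levels(st$group), c("low", "high"))
  # all-equal scores refuse stratification
  fm0 <- fm; fm0$coef[] <- 0
  expect_error(stratify_and_test(fm0, x, time, rep(1, n)), "refused")
  # even n with distinct scores -> equal groups
  set.seed(15)
  xq <- cbind(f = rnorm(50))
  fmq <- fm; fmq$features <- "f"; fmq$coef <- c(f = 1)
  stq <- stratify_and_test(fmq, xq, rexp(50), rep(1, 50))
  expect_equal(sum(stq$group == "low"), 25)
})

test_that("a frozen model transfers to an external cohort without refitting", {
  set.seed(16)
  n <- 250
  gen <- function(n) {
    x <- cbind(f1 = rbinom(n, 1, 0.4), f2 = rbinom(n, 1, 0.4))
    lp <- log(2.5) * x[, "f1"]
    list(x = x, time = rexp(n, 0.01 * exp(lp)), event = rep(1, n))
  }
  tr <- gen(n); ext <- gen(n)
  fm <- fit_final_model(tr$x, tr$time, tr$event, colnames(tr$x))
  ci_int <- evaluate_external(fm, tr$x, tr$time, tr$event)
  ci_ext <- evaluate_external(fm, ext$x, ext$time, ext$event)
  expect_lt(abs(ci_int - ci_ext), 0.08)          # generalizes within noise
  expect_identical(evaluate_external(fm, ext$x, ext$time, ext$event), ci_ext)
  # permuted survival: chance level
  set.seed(17)
  perm <- sample(n)
  ci_perm <- evaluate_external(fm, ext$x, ext$time[perm], ext$event[perm])
  expect_lt(abs(ci_perm - 0.5), 0.06)
  gone <- fm$features[1]
  expect_error(
    evaluate_external(fm, ext$x[, setdiff(colnames(ext$x), gone), drop = FALSE],
                      ext$time, ext$event),
    gone, fixed = TRUE)
})

test_that("the reliability flag is the median c-index band check", {
  expect_true(reliability_flag(mk_runs(c(0.56, 0.58, 0.60), list("A", "A", "A"))))
  expect_false(reliability_flag(mk_runs(c(0.50, 0.52, 0.54), list("A", "A", "A"))))
  expect_false(reliability_flag(mk_runs(c(0.88, 0.90, 0.92), list("A", "A", "A"))))
  expect_equal(attr(reliability_flag(mk_runs(0.58, list("A"))), "median_ci"), 0.58)
})
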