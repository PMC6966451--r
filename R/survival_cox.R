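#' Cancer types eligible for survival modeling
#'
#' A cohort enters the survival analysis when, after excluding patients
#' without any (filtered) CNV, it retains at least `min_n` patients of whom
#' at least `min_event_rate` had a lethal outcome.
#'
#' @param clinical data.frame from [read_clinical_table()].
#' @param patients_with_cnvs optional character vector; patients outside it
#'   are excluded before applying the thresholds.
#' @param min_n minimum cohort size (default 100).
#' @param min_event_rate minimum death rate (default 0.10).
#' @return data.frame: cancer_type, n, events, event_rate, eligible.
#' @export
eligible_cohorts <- function(clinical, patients_with_cnvs = NULL,
                             min_n = 100, min_event_rate = 0.10) {
  if (!is.null(patients_with_cnvs)) {
    clinical <- clinical[clinical$patient_id %in% patients_with_cnvs, , drop = FALSE]
  }
  agg <- stats::aggregate(event ~ cancer_type, data = clinical,
                          FUN = function(e) c(n = length(e), events = sum(e)))
  out <- data.frame(cancer_type = agg$cancer_type,
                    n = agg$event[, "n"], events = agg$event[, "events"])
  out$event_rate <- out$events / out$n
  out$eligible <- out$n >= min_n & out$event_rate >= min_event_rate
  out
}

#' Encode the binary feature table for survival models
#'
#' Features are the per-patient CNV presence indicators for the enriched
#' TADs, plus `age_high` (1 when age exceeds the training-set median age)
#' and `sex` (1 female, 0 male). Constant columns — e.g. sex in a
#' single-sex cancer — are dropped with a warning.
#'
#' @param tad_matrix binary patients x TADs matrix from [overlap_matrix()],
#'   already restricted to the enriched TADs.
#' @param age numeric ages, aligned with the rows of `tad_matrix`.
#' @param sex `"female"`/`"male"` vector aligned with the rows.
#' @param train_median_age the median age of the training set; ages
#'   strictly above it are encoded 1.
#' @return Binary numeric matrix with columns `<tad ids>`, `age_high`, `sex`.
#' @export
encode_features <- function(tad_matrix, age, sex, train_median_age) {
  stopifnot(nrow(tad_matrix) == length(age), length(age) == length(sex))
  x <- cbind(tad_matrix,
             age_high = as.integer(age > train_median_age),
             sex = as.integer(tolower(sex) == "female"))
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  x
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose risk ordering matches the
#' observed survival ordering; tied risk scores count 0.5. Higher scores
#' must mean higher risk (shorter survival): 1 is perfect, 0.5 random.
#'
#' @param score per-patient risk scores.
#' @param time survival or censoring times.
#' @param event 1 = death observed, 0 = censored.
#' @return Concordance in \[0, 1\].
#' @export
concordance_index <- function(score, time, event) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  fit <- survival::concordance(survival::Surv(time, event) ~ score,
                               reverse = TRUE)
  npairs <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  if (npairs == 0) stop("no comparable pairs; concordance undefined")
  unname(fit$concordance)
}

# Rank features by |coefficient| (ties by name), return top `k` with their
# coefficients. `beta` is a named coefficient vector.
.top_features <- function(beta, k) {
  beta <- beta[beta != 0]
  if (!length(beta)) return(beta)
  ord <- order(-abs(beta), names(beta))
  beta[ord[seq_len(min(k, length(beta)))]]
}

# Entry order of features along a glmnet regularization path (first lambda
# index at which the coefficient becomes nonzero; never-entering last).
.path_entry_order <- function(fit) {
  B <- as.matrix(fit$beta)
  first <- apply(B != 0, 1, function(r) if (any(r)) which(r)[1] else Inf)
  names(sort(first))
}

#' Repeated train/test LASSO Cox runs
#'
#' Repeats `K` times: split the cohort into a training (fraction `split`)
#' and a test set; fit an L1-penalized Cox model on the training set with
#' the regularization weight chosen by `folds`-fold cross-validation at the
#' minimum partial-likelihood deviance; keep the `top` features with the
#' largest absolute coefficients; and score the held-out patients with
#' those coefficients to obtain a test concordance index. When the
#' cross-validation fails to converge the run falls back to ranking
#' features by their order of entry into the regularization path. Runs
#' whose training set has fewer than two events are recorded as failed.
#'
#' @param features binary feature matrix (patients x features) from
#'   [encode_features()].
#' @param time,event survival endpoints aligned with the feature rows.
#' @param K number of repetitions (default 1000).
#' @param split training fraction (default 2/3).
#' @param folds cross-validation folds (default 5).
#' @param top number of features retained per run (default 10).
#' @param seed master seed; per-run seeds are drawn from it once, so runs
#'   are reproducible and independent of `K` ordering.
#' @param ages optional raw ages; when given, the `age_high` column is
#'   re-binarized within each run against the training-set median age.
#' @param refit_features optional `function(train_idx)` returning a
#'   replacement feature matrix for a run (all patients x features), for
#'   pipelines that recompute TAD enrichment on each training split.
#' @return List of class `model_runs`; each element has `train`, `test`,
#'   `selected` (named coefficient vector), `lambda`, `ci`, `converged`,
#'   `failed`.
#' @export
run_repeated_models <- function(features, time, event, K = 1000,
                                split = 2 / 3, folds = 5, top = 10,
                                seed = NULL, ages = NULL,
                                refit_features = NULL) {
  n <- nrow(features)
  stopifnot(length(time) == n, length(event) == n)
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, K)
  runs <- vector("list", K)
  for (i in seq_len(K)) {
    set.seed(run_seeds[i])
    tr <- sort(sample(n, floor(split * n)))
    te <- setdiff(seq_len(n), tr)
    x <- if (is.null(refit_features)) features else refit_features(tr)
    if (!is.null(ages)) {
      med <- stats::median(ages[tr])
      if ("age_high" %in% colnames(x)) {
        x[, "age_high"] <- as.integer(ages > med)
      }
    }
    run <- list(train = tr, test = te, selected = numeric(0),
                lambda = NA_real_, ci = NA_real_, converged = TRUE,
                failed = FALSE)
    if (sum(event[tr]) < 2 || sum(event[te]) < 1) {
      run$failed <- TRUE
      runs[[i]] <- run
      next
    }
    y <- survival::Surv(time[tr], event[tr])
    beta <- tryCatch({
      cv <- glmnet::cv.glmnet(x[tr, , drop = FALSE], y, family = "cox",
                              alpha = 1, nfolds = folds)
      run$lambda <- cv$lambda.min
      b <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
      .top_features(b, top)
    }, error = function(e) NULL)
    if (is.null(beta)) {
      # cross-validation failed: rank by entry into the regularization path
      run$converged <- FALSE
      beta <- tryCatch({
        fit <- glmnet::glmnet(x[tr, , drop = FALSE], y, family = "cox", alpha = 1)
        keep <- utils::head(.path_entry_order(fit), top)
        b <- as.matrix(stats::coef(fit, s = min(fit$lambda)))[, 1]
        b <- b[names(b) %in% keep & b != 0]
        .top_features(b, top)
      }, error = function(e) NULL)
    }
    if (is.null(beta)) {
      run$failed <- TRUE
      runs[[i]] <- run
      next
    }
    run$selected <- beta
    risk <- if (length(beta)) {
      as.numeric(x[te, names(beta), drop = FALSE] %*% beta)
    } else {
      rep(0, length(te))
    }
    run$ci <- tryCatch(concordance_index(risk, time[te], event[te]),
                       error = function(e) NA_real_)
    if (is.na(run$ci)) run$failed <- TRUE
    runs[[i]] <- run
  }
  failed <- vapply(runs, `[[`, TRUE, "failed")
  if (any(failed)) {
    message(sprintf("%d of %d runs failed (degenerate split) and are excluded",
                    sum(failed), K))
  }
  structure(runs[!failed], K_requested = K, class = "model_runs")
}

#' @export
print.model_runs <- function(x, ...) {
  ci <- vapply(x, `[[`, 0, "ci")
  cat(sprintf("%d completed LASSO Cox runs; median test c-index %.3f (IQR %.3f-%.3f)\n",
              length(x), stats::median(ci),
              stats::quantile(ci, .25), stats::quantile(ci, .75)))
  invisible(x)
}

#' Aggregate feature selections across runs
#'
#' Each completed run i receives a raw weight
#' `w_i = (1/K) * exp(ln(2) * devCI_i / 0.1)` when its test concordance
#' `CI_i` is at least 0.5 and `w_i = 0` otherwise, where
#' `devCI_i = CI_i - mean(CI)`: a run 0.1 of c-index above the mean counts
#' twice as much as an average run. Weights are normalized to sum to 1 and
#' each feature's aggregated weight `P_j` is the summed normalized weight
#' of the runs that selected it, so `P_j = 1` exactly when feature j was
#' selected in every positively weighted run.
#'
#' @param runs a `model_runs` object.
#' @param universe feature universe; defaults to the union of features ever
#'   selected across runs.
#' @return data.frame of class `aggregated_features`: feature, n_selected,
#'   P; sorted by decreasing P (ties by feature name).
#' @export
aggregate_features <- function(runs, universe = NULL) {
  K <- length(runs)
  if (!K) stop("no completed runs")
  ci <- vapply(runs, `[[`, 0, "ci")
  if (all(ci < 0.5)) stop("no informative runs (all c-indices below 0.5)")
  dev <- ci - mean(ci)
  w <- ifelse(ci >= 0.5, exp(log(2) * dev / 0.1) / K, 0)
  wn <- w / sum(w)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(runs, function(r) names(r$selected)))))
  }
  P <- vapply(universe, function(f) {
    sum(wn[vapply(runs, function(r) f %in% names(r$selected), TRUE)])
  }, 0)
  out <- data.frame(feature = universe,
                    n_selected = vapply(universe, function(f) {
                      sum(vapply(runs, function(r) f %in% names(r$selected), TRUE))
                    }, 0L),
                    P = unname(P), stringsAsFactors = FALSE)
  out <- out[order(-out$P, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, weights = wn, mean_ci = mean(ci),
            class = c("aggregated_features", "data.frame"))
}

#' Median-c-index reliability flag for a set of runs
#'
#' A cohort's TAD-based model is considered reliable when the median test
#' c-index over all completed runs lies within \[0.55, 0.8\]: clearly above
#' chance, but not so high as to suggest leakage or a degenerate cohort.
#'
#' @param runs a `model_runs` object.
#' @param band inclusive reliability band (default `c(0.55, 0.8)`).
#' @return `TRUE`/`FALSE`, with the median c-index as attribute `median_ci`.
#' @export
reliability_flag <- function(runs, band = c(0.55, 0.8)) {
  if (!length(runs)) stop("no runs")
  m <- stats::median(vapply(runs, `[[`, 0, "ci"))
  structure(m >= band[1] && m <= band[2], median_ci = m)
}

#' Final Cox model with backward elimination
#'
#' Fits an unpenalized Cox proportional-hazards model on the candidate
#' features (at most the top ten aggregated features), then iteratively
#' removes the feature with the largest Wald p-value until every remaining
#' coefficient is significant at `p_cut`. Exactly collinear duplicates are
#' resolved beforehand by keeping the alphabetically first column.
#' Benjamini-Hochberg q-values are reported for the retained features;
#' retention itself is governed by the raw p-values, and features with
#' q > 0.05 carry a flag.
#'
#' @param features binary feature matrix (all patients).
#' @param time,event survival endpoints.
#' @param candidates character vector of candidate feature names (<= 10).
#' @param p_cut Wald significance threshold for retention (default 0.05).
#' @return List of class `final_model`: coef, hazard_ratio, p, q, flagged,
#'   features, n, empty.
#' @export
fit_final_model <- function(features, time, event, candidates,
                            p_cut = 0.05) {
  candidates <- intersect(candidates, colnames(features))
  if (!length(candidates)) stop("no candidate features present in the table")
  x <- features[, sort(candidates), drop = FALSE]
  # drop exact duplicates deterministically (keep first by name)
  if (ncol(x) > 1) {
    dup <- duplicated(t(x))
    if (any(dup)) {
      warning("dropping collinear duplicate feature(s): ",
              paste(colnames(x)[dup], collapse = ", "))
      x <- x[, !dup, drop = FALSE]
    }
  }
  repeat {
    if (ncol(x) == 0) {
      return(structure(list(coef = numeric(0), hazard_ratio = numeric(0),
                            p = numeric(0), q = numeric(0),
                            flagged = logical(0), features = character(0),
                            n = length(time), empty = TRUE),
                       class = "final_model"))
    }
    # genomic feature ids are not syntactic names; fit under safe aliases
    df <- as.data.frame(x)
    colnames(df) <- sprintf("f%d", seq_len(ncol(df)))
    fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df)
    beta <- stats::coef(fit)
    names(beta) <- colnames(x)
    if (anyNA(beta)) {               # residual collinearity
      drop <- names(beta)[which(is.na(beta))[1]]
      x <- x[, setdiff(colnames(x), drop), drop = FALSE]
      next
    }
    p <- summary(fit)$coefficients[, "Pr(>|z|)"]
    names(p) <- names(beta)
    if (all(p <= p_cut)) break
    worst <- names(p)[order(-p, names(p))][1]
    x <- x[, setdiff(colnames(x), worst), drop = FALSE]
  }
  q <- stats::p.adjust(p, method = "BH")
  structure(list(coef = beta, hazard_ratio = exp(beta), p = p, q = q,
                 flagged = q > 0.05, features = names(beta),
                 n = length(time), empty = FALSE),
            class = "final_model")
}

#' @export
print.final_model <- function(x, ...) {
  if (x$empty) {
    cat("final Cox model: empty (no feature reached significance)\n")
    return(invisible(x))
  }
  df <- data.frame(coef = round(x$coef, 4),
                   HZ = round(x$hazard_ratio, 3),
                   p = signif(x$p, 3), q = signif(x$q, 3),
                   flag = ifelse(x$flagged, "+", ""))
  cat(sprintf("final Cox model on %d patients, %d prognostic feature(s):\n",
              x$n, length(x$features)))
  print(df)
  invisible(x)
}

#' Risk scores from a final model
#'
#' @param model a `final_model`.
#' @param features feature matrix containing the model's features.
#' @return Numeric per-patient risk score (linear predictor
#'   `sum(coef * feature)`).
#' @export
risk_scores <- function(model, features) {
  miss <- setdiff(model$features, colnames(features))
  if (length(miss)) {
    stop("feature column(s) missing from the table: ",
         paste(miss, collapse = ", "))
  }
  as.numeric(features[, model$features, drop = FALSE] %*% model$coef)
}

#' Median-split risk stratification with log-rank test
#'
#' Computes per-patient risk scores, splits patients at the median score
#' (scores at or below the median are low risk), and compares the two
#' groups' survival with Kaplan-Meier estimates and a log-rank test.
#'
#' @param model a `final_model` with at least one feature.
#' @param features feature matrix for the cohort.
#' @param time,event survival endpoints.
#' @return List of class `risk_stratification`: score, group, logrank_chisq,
#'   p_value, km (a `survfit` object).
#' @export
stratify_and_test <- function(model, features, time, event) {
  if (model$empty) stop("cannot stratify: the final model has no features")
  score <- risk_scores(model, features)
  if (length(unique(score)) == 1) {
    stop("all risk scores identical; stratification refused")
  }
  group <- factor(ifelse(score <= stats::median(score), "low", "high"),
                  levels = c("low", "high"))
  if (nlevels(droplevels(group)) < 2) {
    stop("median split produced a single group; stratification refused")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  km <- survival::survfit(survival::Surv(time, event) ~ group)
  structure(list(score = score, group = group,
                 logrank_chisq = sd$chisq,
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 km = km),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat(sprintf("risk stratification: %d low / %d high; log-rank p = %.3g\n",
              sum(x$group == "low"), sum(x$group == "high"), x$p_value))
  invisible(x)
}

#' Apply a frozen final model to an independent cohort
#'
#' Scores the external patients with the trained coefficients and returns
#' the concordance index on the external cohort; no refitting takes place.
#'
#' @param model a `final_model`.
#' @param features external feature matrix (must contain the model's
#'   feature columns; an informative error lists any that are missing).
#' @param time,event external survival endpoints.
#' @return Concordance index in \[0, 1\].
#' @export
evaluate_external <- function(model, features, time, event) {
  concordance_index(risk_scores(model, features), time, event)
}
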