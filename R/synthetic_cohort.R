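#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#' Defaults describe a desk-scale study: a three-chromosome 150-Mb genome
#' organized in TADs whose sizes are log-normal with a median around 1 Mb
#' separated by short boundary regions, a dozen tissues in clades, 100
#' patients per cancer type carrying a negative-binomial number of CNVs
#' with log-uniform lengths between 1 kb and 10 Mb, and exponential
#' proportional-hazards survival with independent uniform censoring.
#'
#' @param seed master seed; every generator draws from it reproducibly.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param tad_meanlog,tad_sdlog log-normal TAD size parameters (bp).
#' @param gap_meanlog,gap_sdlog log-normal inter-TAD gap parameters (bp).
#' @param tissues character vector of tissue ids.
#' @param conditions `"normal"`/`"cancer"` per tissue.
#' @param clades list of character vectors partitioning the tissues.
#' @param clade_share correlation of TAD-map perturbations within a clade
#'   (0 = independent, 1 = identical within clade).
#' @param jitter_sd boundary jitter standard deviation in bp.
#' @param p_split,p_fuse per-TAD split and per-adjacent-pair fusion
#'   probabilities for the tissue maps.
#' @param n_patients patients per cancer type.
#' @param cancer_types character vector of cohort labels.
#' @param cnv_mu,cnv_size negative-binomial mean and dispersion of the
#'   per-patient background CNV count.
#' @param cnv_len_range log-uniform CNV length range in bp.
#' @param enriched_tads integer indices (into the base map's TADs) of
#'   spiked TADs.
#' @param enrich_factor target patient-recurrence fold over background for
#'   the spiked TADs.
#' @param causal_tads indices (into `enriched_tads`) of TADs whose CNV
#'   presence carries a survival effect.
#' @param log_hr log hazard ratio of each causal TAD feature.
#' @param beta_age,beta_sex log hazard ratios for the age-high and female
#'   indicators.
#' @param censor_frac target fraction of censored patients.
#' @param baseline_hazard exponential baseline hazard (per day).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_sizes = c(chr1 = 6e7, chr2 = 5e7, chr3 = 4e7),
                       tad_meanlog = log(1e6), tad_sdlog = 0.35,
                       gap_meanlog = log(8e4), gap_sdlog = 0.5,
                       tissues = sprintf("T%02d", 1:12),
                       conditions = rep(c("normal", "cancer"), c(8, 4)),
                       clades = NULL,
                       clade_share = 0.5,
                       jitter_sd = 2e4,
                       p_split = 0.05, p_fuse = 0.05,
                       n_patients = 100,
                       cancer_types = "SIM",
                       cnv_mu = 30, cnv_size = 2,
                       cnv_len_range = c(1e3, 1e7),
                       enriched_tads = integer(0),
                       enrich_factor = 3,
                       causal_tads = integer(0),
                       log_hr = log(2),
                       beta_age = log(1.5), beta_sex = 0,
                       censor_frac = 0.25,
                       baseline_hazard = log(2) / 1000) {
  if (is.null(clades)) {
    clades <- split(tissues, rep(seq_len(ceiling(length(tissues) / 4)),
                                 each = 4)[seq_along(tissues)])
  }
  stopifnot(length(conditions) == length(tissues),
            all(conditions %in% c("normal", "cancer")),
            all(unlist(clades) %in% tissues),
            clade_share >= 0, clade_share <= 1,
            p_split >= 0, p_split <= 1, p_fuse >= 0, p_fuse <= 1,
            enrich_factor > 0, censor_frac >= 0, censor_frac < 1)
  structure(as.list(environment()), class = "sim_config")
}

# TAD sizes/gaps drawn on a 1-kb grid until the chromosome is full.
.simulate_base_chrom <- function(size, cfg) {
  pos <- round(stats::rlnorm(1, cfg$gap_meanlog, cfg$gap_sdlog) / 1000) * 1000
  starts <- numeric(0); ends <- numeric(0)
  while (TRUE) {
    len <- round(stats::rlnorm(1, cfg$tad_meanlog, cfg$tad_sdlog) / 1000) * 1000
    len <- max(len, 50000)
    if (pos + len > size) break
    starts <- c(starts, pos); ends <- c(ends, pos + len)
    gap <- round(stats::rlnorm(1, cfg$gap_meanlog, cfg$gap_sdlog) / 1000) * 1000
    pos <- pos + len + max(gap, 1000)
  }
  data.frame(start = starts, end = ends)
}

#' Simulate a base TAD map
#'
#' Draws the "true" domain organization: per chromosome, TADs with
#' log-normal sizes on a 1-kb grid separated by short log-normal gaps.
#'
#' @param config a `sim_config`.
#' @return A `tad_map` (sample_id `"base"`).
#' @export
simulate_base_map <- function(config) {
  set.seed(config$seed)
  pieces <- lapply(names(config$chrom_sizes), function(ch) {
    df <- .simulate_base_chrom(config$chrom_sizes[[ch]], config)
    if (nrow(df)) cbind(chrom = ch, df) else NULL
  })
  tad_map(do.call(rbind, pieces), "base", "normal", config$chrom_sizes)
}

# Apply split/fusion edits to a map. split_ids: row indices to cut in two
# (with a small internal gap); fuse_pairs: list of index vectors of
# consecutive TADs to merge (gap absorbed).
#' Apply split and fusion edits to a TAD map
#'
#' Splits cut a TAD into two pieces separated by a small gap around a
#' breakpoint (midpoint by default); fusions merge runs of consecutive
#' TADs, absorbing the gaps between them. Used to derive perturbed tissue
#' maps and labeled cancer genomes from the base map.
#'
#' @param map a `tad_map`.
#' @param split_ids integer row indices of TADs to split.
#' @param fuse_groups list of integer vectors of consecutive row indices to
#'   merge.
#' @param split_gap gap inserted at a split, in bp (default 40000).
#' @param sample_id,condition labels for the edited map.
#' @return A `tad_map`.
#' @export
apply_tad_edits <- function(map, split_ids = integer(0),
                            fuse_groups = list(), split_gap = 4e4,
                            sample_id = attr(map, "sample_id"),
                            condition = attr(map, "condition")) {
  df <- as.data.frame(map)
  drop <- logical(nrow(df))
  extra <- list()
  for (g in fuse_groups) {
    g <- sort(g)
    stopifnot(all(diff(g) == 1), all(df$chrom[g] == df$chrom[g[1]]))
    df$end[g[1]] <- df$end[g[length(g)]]
    drop[g[-1]] <- TRUE
  }
  split_ids <- setdiff(split_ids, unlist(fuse_groups))
  for (i in split_ids) {
    mid <- round((df$start[i] + df$end[i]) / 2 / 1000) * 1000
    lo <- max(df$start[i] + 50000, mid - split_gap / 2)
    hi <- min(df$end[i] - 50000, mid + split_gap / 2)
    if (lo >= hi) next
    extra[[length(extra) + 1]] <- data.frame(chrom = df$chrom[i],
                                             start = hi, end = df$end[i])
    df$end[i] <- lo
  }
  out <- rbind(df[!drop, c("chrom", "start", "end")],
               do.call(rbind, extra))
  tad_map(out, sample_id, condition)
}

#' Simulate correlated multi-tissue TAD maps
#'
#' Starts from the base map and perturbs it per tissue: every boundary is
#' jittered by Gaussian noise on the 1-kb grid, and TADs are split or
#' adjacent TADs fused with the configured probabilities. Tissues in the
#' same clade share a fraction `clade_share` of the jitter variance and of
#' the split/fusion events, so related tissues get related maps. Jitter
#' that would invert or overlap intervals is resampled (then truncated as
#' a last resort).
#'
#' @param config a `sim_config`.
#' @return List: `maps` (list of `tad_map`, one per tissue), `base` (the
#'   base `tad_map`).
#' @export
simulate_tad_maps <- function(config) {
  base <- simulate_base_map(config)
  set.seed(config$seed + 1L)
  rho <- config$clade_share
  nt <- nrow(base)
  clade_of <- stats::setNames(rep(names(config$clades), lengths(config$clades)),
                              unlist(config$clades))
  # shared per-clade perturbation draws
  clade_jit_s <- clade_jit_e <- clade_split <- clade_fuse <- list()
  for (cl in names(config$clades)) {
    clade_jit_s[[cl]] <- stats::rnorm(nt, 0, config$jitter_sd)
    clade_jit_e[[cl]] <- stats::rnorm(nt, 0, config$jitter_sd)
    clade_split[[cl]] <- stats::runif(nt)
    clade_fuse[[cl]] <- stats::runif(nt)
  }
  maps <- vector("list", length(config$tissues))
  names(maps) <- config$tissues
  for (k in seq_along(config$tissues)) {
    tis <- config$tissues[k]
    cl <- clade_of[[tis]]
    jit_s <- sqrt(rho) * clade_jit_s[[cl]] +
      sqrt(1 - rho) * stats::rnorm(nt, 0, config$jitter_sd)
    jit_e <- sqrt(rho) * clade_jit_e[[cl]] +
      sqrt(1 - rho) * stats::rnorm(nt, 0, config$jitter_sd)
    u_split <- rho * clade_split[[cl]] + (1 - rho) * stats::runif(nt)
    u_fuse <- rho * clade_fuse[[cl]] + (1 - rho) * stats::runif(nt)
    df <- as.data.frame(base)
    s <- df$start + round(jit_s / 1000) * 1000
    e <- df$end + round(jit_e / 1000) * 1000
    # repair: clip to chromosome, resolve inversions/overlaps
    for (ch in unique(df$chrom)) {
      i <- which(df$chrom == ch)
      size <- config$chrom_sizes[[ch]]
      s[i] <- pmax(0, pmin(s[i], size - 1000))
      e[i] <- pmax(1000, pmin(e[i], size))
      prev_end <- 0
      for (j in i) {
        if (s[j] < prev_end) s[j] <- prev_end
        if (e[j] <= s[j] + 1000) e[j] <- s[j] + 1000
        if (e[j] > size) e[j] <- size
        prev_end <- e[j]
      }
    }
    df$start <- s; df$end <- e
    m <- tad_map(df, tis, config$conditions[k])
    split_ids <- which(u_split < config$p_split)
    fuse_groups <- list()
    cand <- which(u_fuse < config$p_fuse)
    for (j in cand) {
      if (j < nrow(m) && m$chrom[j] == m$chrom[j + 1]) {
        fuse_groups[[length(fuse_groups) + 1]] <- c(j, j + 1)
      }
    }
    # avoid chained/overlapping fusions
    used <- integer(0)
    fuse_groups <- Filter(function(g) {
      ok <- !any(g %in% used)
      if (ok) used <<- c(used, g)
      ok
    }, fuse_groups)
    maps[[k]] <- apply_tad_edits(m, split_ids, fuse_groups,
                                 sample_id = tis,
                                 condition = config$conditions[k])
  }
  list(maps = maps, base = base)
}

#' Simulate clade-structured expression counts
#'
#' Negative-binomial counts whose log-means carry a shared clade effect on
#' a subset of genes, so that correlation-based clustering recovers the
#' generating clade topology and closely related tissues end up sharing
#' weight.
#'
#' @param config a `sim_config`.
#' @param n_genes number of genes (default 3000).
#' @param clade_sd standard deviation of the clade effect on log2 scale.
#' @param noise_sd per-tissue log2 noise.
#' @param nb_size negative-binomial dispersion.
#' @return genes x tissues count matrix.
#' @export
simulate_expression <- function(config, n_genes = 3000, clade_sd = 1.5,
                                noise_sd = 0.3, nb_size = 10) {
  set.seed(config$seed + 2L)
  tissues <- config$tissues
  base_mu <- stats::rnorm(n_genes, 5, 2)          # log2 scale
  clade_fx <- sapply(names(config$clades), function(cl) {
    stats::rnorm(n_genes, 0, clade_sd)
  })
  clade_of <- stats::setNames(rep(names(config$clades), lengths(config$clades)),
                              unlist(config$clades))
  counts <- sapply(tissues, function(tis) {
    lmu <- base_mu + clade_fx[, clade_of[[tis]]] +
      stats::rnorm(n_genes, 0, noise_sd)
    stats::rnbinom(n_genes, mu = pmax(2^lmu, 0.1), size = nb_size)
  })
  rownames(counts) <- sprintf("gene%05d", seq_len(n_genes))
  counts
}

# One CNV overlapping a given TAD: uniform among overlapping placements,
# attributes drawn conditional on passing the standard filters.
.spiked_cnv <- function(tad, chrom_size, cfg) {
  repeat {
    len <- round(exp(stats::runif(1, log(max(cfg$cnv_len_range[1], 1001)),
                                  log(cfg$cnv_len_range[2]))))
    probes <- max(1, stats::rpois(1, len / 1500))
    if (len > 1000 && probes >= 10) break
  }
  lo <- max(0, tad$start - len + 1)
  hi <- min(chrom_size - len, tad$end - 1)
  start <- floor(stats::runif(1, lo, hi + 1))
  mean_ <- sample(c(-1, 1), 1) * stats::runif(1, 0.2, 0.8)
  list(start = start, end = start + len, num_probes = probes,
       segment_mean = mean_)
}

#' Simulate patient CNV segments with spiked per-TAD recurrence
#'
#' Per patient, a negative-binomial number of background CNVs is placed
#' uniformly over the genome with log-uniform lengths; segment means come
#' from a two-component mixture straddling the +/-0.1 filter threshold and
#' probe counts scale with length, so the standard filters are genuinely
#' exercised. TADs listed in `config$enriched_tads` then receive extra
#' patient placements, drawn conditional on passing the filters, until
#' their post-filter patient recurrence reaches `enrich_factor` times the
#' background recurrence observed for that TAD (capped at 95%). Spiking
#' adds placements rather than reweighting, so kept-CNV length
#' distributions are identical between spiked and background TADs.
#'
#' @param config a `sim_config`.
#' @param tads base-map TAD table (data.frame chrom/start/end), typically
#'   `simulate_tad_maps(config)$base`.
#' @return `cnv_segments` data.frame (one row per segment, pre-filtering),
#'   with attribute `truth` listing the spiked tad row indices.
#' @export
simulate_cnvs <- function(config, tads) {
  set.seed(config$seed + 3L)
  sizes <- config$chrom_sizes
  patients <- unlist(lapply(config$cancer_types, function(ct) {
    sprintf("%s-P%03d", ct, seq_len(config$n_patients))
  }))
  types <- rep(config$cancer_types, each = config$n_patients)
  rows <- vector("list", length(patients))
  for (p in seq_along(patients)) {
    n_cnv <- stats::rnbinom(1, mu = config$cnv_mu, size = config$cnv_size)
    if (n_cnv == 0) {
      rows[[p]] <- NULL
      next
    }
    len <- round(exp(stats::runif(n_cnv, log(config$cnv_len_range[1]),
                                  log(config$cnv_len_range[2]))))
    ch <- character(n_cnv); start <- numeric(n_cnv)
    for (j in seq_len(n_cnv)) {
      slots <- pmax(sizes - len[j] + 1, 0)
      ch[j] <- sample(names(sizes), 1, prob = slots)
      start[j] <- floor(stats::runif(1) * slots[ch[j]])
    }
    noise <- stats::runif(n_cnv) < 0.15
    segm <- ifelse(noise, stats::rnorm(n_cnv, 0, 0.05),
                   sample(c(-1, 1), n_cnv, TRUE) * stats::runif(n_cnv, 0.2, 0.8))
    rows[[p]] <- data.frame(patient_id = patients[p], cancer_type = types[p],
                            chrom = ch, start = start, end = start + len,
                            num_probes = pmax(1, stats::rpois(n_cnv, len / 1500)),
                            segment_mean = segm, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # spike recurrence in the enriched TADs
  if (length(config$enriched_tads)) {
    kept <- filter_cnvs(structure(out, class = c("cnv_segments", "data.frame")))
    for (ti in config$enriched_tads) {
      tad <- tads[ti, ]
      hit <- unique(kept$patient_id[kept$chrom == tad$chrom &
                                      kept$start < tad$end &
                                      kept$end > tad$start])
      r0 <- length(hit) / length(patients)
      target <- min(0.95, config$enrich_factor * max(r0, 1 / length(patients)))
      extra_n <- round((target - r0) * length(patients))
      if (extra_n <= 0) next
      pool <- setdiff(patients, hit)
      chosen <- sample(pool, min(extra_n, length(pool)))
      add <- lapply(chosen, function(p) {
        cnv <- .spiked_cnv(tad, sizes[[tad$chrom]], config)
        data.frame(patient_id = p, cancer_type = types[match(p, patients)],
                   chrom = tad$chrom, start = cnv$start, end = cnv$end,
                   num_probes = cnv$num_probes, segment_mean = cnv$segment_mean,
                   stringsAsFactors = FALSE)
      })
      out <- rbind(out, do.call(rbind, add))
    }
  }
  out <- out[order(out$patient_id, out$chrom, out$start), ]
  rownames(out) <- NULL
  out$sign <- ifelse(out$segment_mean > 0, "gain", "loss")
  structure(out, truth = config$enriched_tads,
            class = c("cnv_segments", "data.frame"))
}

#' Simulate survival records from a proportional-hazards model
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(lp)`, where the linear predictor sums the causal
#' TAD features times their log hazard ratios plus age and sex effects;
#' with an exponential baseline the Cox coefficients equal the generative
#' log hazard ratios exactly. Censoring times are uniform on (0, c_max)
#' with c_max calibrated so the expected censored fraction matches
#' `config$censor_frac`. Ages are N(65, 10) and sex is balanced Bernoulli.
#'
#' @param config a `sim_config`; `causal_tads` indexes columns of
#'   `features` (or use `causal_features` to name them directly).
#' @param features binary patients x features matrix (e.g. from
#'   [overlap_matrix()] on the enriched TADs).
#' @param causal_features optional character vector naming the causal
#'   columns; overrides `config$causal_tads`.
#' @return data.frame: patient_id, cancer_type, time, event, age, sex, and
#'   attribute `truth` with the causal feature names and log hazard ratios.
#' @export
simulate_survival <- function(config, features, causal_features = NULL) {
  set.seed(config$seed + 4L)
  n <- nrow(features)
  if (is.null(causal_features)) {
    causal_features <- colnames(features)[config$causal_tads]
  }
  stopifnot(all(causal_features %in% colnames(features)))
  beta <- rep(config$log_hr, length.out = length(causal_features))
  age <- round(stats::rnorm(n, 65, 10))
  sex <- sample(c("female", "male"), n, TRUE)
  age_high <- as.integer(age > stats::median(age))
  lp <- as.numeric(features[, causal_features, drop = FALSE] %*% beta) +
    config$beta_age * age_high + config$beta_sex * (sex == "female")
  T <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
  if (config$censor_frac <= 0) {
    time <- T; event <- rep(1L, n)
  } else {
    f <- function(cmax) mean(pmin(1, T / cmax)) - config$censor_frac
    cmax <- stats::uniroot(f, c(min(T) / 2, max(T) * 100 / config$censor_frac),
                           extendInt = "yes")$root
    Cens <- stats::runif(n, 0, cmax)
    event <- as.integer(T <= Cens)
    time <- pmin(T, Cens)
  }
  out <- data.frame(
    patient_id = if (!is.null(rownames(features))) rownames(features)
                 else sprintf("P%04d", seq_len(n)),
    cancer_type = rep(config$cancer_types[1], n),
    time = time, event = event, age = age, sex = sex,
    stringsAsFactors = FALSE)
  structure(out, truth = stats::setNames(beta, causal_features))
}
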