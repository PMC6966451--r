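#' Filter somatic CNV segments
#'
#' Keeps segments longer than 1 kb and up to 10 Mb, with an absolute
#' segment mean above 0.1 and at least 10 probes. These cutoffs remove
#' probe-level noise and chromosome-arm events whose interpretation is
#' ambiguous.
#'
#' @param segments `cnv_segments` data.frame (see [read_seg_file()]).
#' @param min_len,max_len length bounds in bp (kept iff
#'   `min_len < length <= max_len`).
#' @param min_abs_mean minimum absolute segment mean (exclusive).
#' @param min_probes minimum probe count (inclusive).
#' @return The filtered segments.
#' @export
filter_cnvs <- function(segments, min_len = 1000, max_len = 1e7,
                        min_abs_mean = 0.1, min_probes = 10) {
  len <- segments$end - segments$start
  keep <- len > min_len & len <= max_len &
    abs(segments$segment_mean) > min_abs_mean &
    segments$num_probes >= min_probes
  segments[keep, , drop = FALSE]
}

#' Sample a fixed-size patient cohort per cancer type
#'
#' Uniformly samples `n` patients without replacement within each cancer
#' type; types with fewer than `n` patients are excluded with a warning.
#'
#' @param patients data.frame with columns patient_id and cancer_type (one
#'   row per patient).
#' @param n patients per type (default 100).
#' @param seed RNG seed for reproducible sampling.
#' @return Subset of `patients` rows.
#' @export
sample_cohort <- function(patients, n = 100, seed = NULL) {
  if (anyDuplicated(patients$patient_id)) stop("duplicated patient_id")
  if (!is.null(seed)) set.seed(seed)
  keep <- list()
  for (ct in sort(unique(patients$cancer_type))) {
    i <- which(patients$cancer_type == ct)
    if (length(i) < n) {
      warning(sprintf("cancer type %s has %d (< %d) patients; excluded",
                      ct, length(i), n))
      next
    }
    keep[[ct]] <- sort(sample(i, n))
  }
  patients[unlist(keep), , drop = FALSE]
}

#' Binary patient-by-TAD CNV presence matrix
#'
#' Entry (p, t) is 1 when any CNV of patient p overlaps TAD t by at least
#' 1 bp (half-open intervals: abutting segments share no base and do not
#' count). Patients without any CNV among `cnvs` are excluded with a
#' message; pass `patients` to control (and log) the intended row universe.
#'
#' @param cnvs filtered `cnv_segments`.
#' @param tads data.frame of consensus TADs (see [consensus_tads()]).
#' @param patients optional character vector of patient ids the matrix
#'   should be restricted to.
#' @param by_sign if `TRUE`, returns a list with `gain` and `loss` matrices
#'   built from the sign-stratified segments instead of one pooled matrix.
#' @return Binary matrix (patients x TADs), TAD columns named by `tad_id`.
#' @export
overlap_matrix <- function(cnvs, tads, patients = NULL, by_sign = FALSE) {
  if (by_sign) {
    return(list(gain = overlap_matrix(cnvs[cnvs$sign == "gain", ], tads, patients),
                loss = overlap_matrix(cnvs[cnvs$sign == "loss", ], tads, patients)))
  }
  if (is.null(patients)) patients <- sort(unique(cnvs$patient_id))
  absent <- setdiff(patients, unique(cnvs$patient_id))
  if (length(absent)) {
    message(sprintf("excluding %d patient(s) with no CNVs", length(absent)))
    patients <- setdiff(patients, absent)
  }
  cnvs <- cnvs[cnvs$patient_id %in% patients, , drop = FALSE]
  if (is.null(tads$tad_id)) {
    tads$tad_id <- sprintf("%s:%d-%d", tads$chrom, as.integer(tads$start),
                           as.integer(tads$end))
  }
  m <- matrix(0L, length(patients), nrow(tads),
              dimnames = list(patients, tads$tad_id))
  for (ch in unique(tads$chrom)) {
    it <- which(tads$chrom == ch)
    ic <- which(cnvs$chrom == ch)
    if (!length(ic)) next
    fo <- IRanges::findOverlaps(.as_iranges(tads[it, ]), .as_iranges(cnvs[ic, ]))
    if (!length(fo)) next
    pid <- cnvs$patient_id[ic][S4Vectors::subjectHits(fo)]
    m[cbind(match(pid, patients), it[S4Vectors::queryHits(fo)])] <- 1L
  }
  m
}

# Distinct-patient CNV count for a batch of query regions.
# queries: data.frame(chrom, start, end); returns integer vector.
.patient_hit_counts <- function(queries, cnvs) {
  out <- integer(nrow(queries))
  for (ch in unique(queries$chrom)) {
    iq <- which(queries$chrom == ch)
    ic <- which(cnvs$chrom == ch)
    if (!length(ic)) next
    fo <- IRanges::findOverlaps(.as_iranges(queries[iq, ]), .as_iranges(cnvs[ic, ]))
    if (!length(fo)) next
    dt <- data.table::data.table(q = S4Vectors::queryHits(fo),
                                 p = cnvs$patient_id[ic][S4Vectors::subjectHits(fo)])
    cnt <- dt[, list(n = data.table::uniqueN(p)), by = "q"]
    out[iq[cnt$q]] <- cnt$n
  }
  out
}

# TRUE for each query overlapping any of `regions` by >= 1 bp.
.any_overlap <- function(queries, regions) {
  out <- logical(nrow(queries))
  for (ch in unique(queries$chrom)) {
    iq <- which(queries$chrom == ch)
    ir <- which(regions$chrom == ch)
    if (!length(ir)) next
    out[iq] <- IRanges::overlapsAny(.as_iranges(queries[iq, ]),
                                    .as_iranges(regions[ir, ]))
  }
  out
}

# Uniform placement of same-length random regions: chromosome chosen with
# probability proportional to the number of valid start positions.
.random_regions <- function(len, n, chrom_sizes) {
  slots <- pmax(chrom_sizes - len + 1, 0)   # pmax(first, ...) keeps names
  if (sum(slots) == 0) {
    stop("region of length ", len, " exceeds every chromosome")
  }
  ch <- sample(names(chrom_sizes), n, replace = TRUE, prob = slots)
  start <- floor(stats::runif(n) * slots[ch])
  data.frame(chrom = ch, start = start, end = start + len)
}

#' Permutation test for CNV enrichment and depletion per TAD
#'
#' For each consensus TAD, draws `n_perm` random regions of identical
#' length placed uniformly over all valid genome positions (never crossing
#' a chromosome end), and counts for each the number of patients with at
#' least 1 bp of CNV overlap. The TAD's observed patient count is compared
#' to this null: `p_enriched` is the fraction of null counts greater than
#' or equal to the observed count and `p_depleted` the fraction less than
#' or equal to it (ties included on both sides). A TAD is called enriched
#' (depleted) when the corresponding empirical p-value is at most `alpha`.
#'
#' @param tads data.frame of consensus TADs.
#' @param cnvs filtered `cnv_segments` for the cohort under test.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_perm number of random regions per TAD (default 1000).
#' @param alpha call threshold on the empirical p-values (default 0.05).
#' @param seed RNG seed.
#' @param plus_one if `TRUE`, uses the (r + 1) / (n + 1) pseudocount
#'   estimator for both p-values instead of the plain fraction.
#' @param mask optional BED-like data.frame of regions random placements
#'   must not touch (rejection-sampled away).
#' @return data.frame of class `enrichment_result`: tad_id, chrom, start,
#'   end, observed, expectation, log2_fold, p_enriched, p_depleted, call.
#' @export
enrichment_test <- function(tads, cnvs, chrom_sizes, n_perm = 1000,
                            alpha = 0.05, seed = NULL, plus_one = FALSE,
                            mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tads$tad_id)) {
    tads$tad_id <- sprintf("%s:%d-%d", tads$chrom, as.integer(tads$start),
                           as.integer(tads$end))
  }
  observed <- .patient_hit_counts(tads, cnvs)
  expectation <- p_enr <- p_dep <- numeric(nrow(tads))
  for (i in seq_len(nrow(tads))) {
    len <- tads$end[i] - tads$start[i]
    rr <- .random_regions(len, n_perm, chrom_sizes)
    if (!is.null(mask)) {
      for (tries in 1:100) {
        hit <- .any_overlap(rr, mask)
        if (!any(hit)) break
        rr[hit, ] <- .random_regions(len, sum(hit), chrom_sizes)
      }
    }
    null <- .patient_hit_counts(rr, cnvs)
    expectation[i] <- mean(null)
    if (plus_one) {
      p_enr[i] <- (sum(null >= observed[i]) + 1) / (n_perm + 1)
      p_dep[i] <- (sum(null <= observed[i]) + 1) / (n_perm + 1)
    } else {
      p_enr[i] <- mean(null >= observed[i])
      p_dep[i] <- mean(null <= observed[i])
    }
  }
  call <- rep("none", nrow(tads))
  call[p_enr <= alpha] <- "enriched"
  call[p_dep <= alpha] <- "depleted"
  call[p_enr <= alpha & p_dep <= alpha] <- "both"
  res <- data.frame(tad_id = tads$tad_id, chrom = tads$chrom,
                    start = tads$start, end = tads$end,
                    observed = observed, expectation = expectation,
                    log2_fold = log2(observed / expectation),
                    p_enriched = p_enr, p_depleted = p_dep,
                    call = call, stringsAsFactors = FALSE)
  structure(res, n_perm = n_perm, alpha = alpha,
            class = c("enrichment_result", "data.frame"))
}

#' Annotate consensus TADs with overlapping genes
#'
#' A gene belongs to every TAD it overlaps by at least 1 bp; genes falling
#' entirely between TADs (e.g. in a TBR) are assigned to none.
#'
#' @param tads data.frame of consensus TADs.
#' @param genes BED-like data.frame (chrom, start, end, name), e.g. from
#'   [read_bed()].
#' @return Named list: for each `tad_id`, the character vector of
#'   overlapping gene names (possibly empty).
#' @export
annotate_genes <- function(tads, genes) {
  if (is.null(tads$tad_id)) {
    tads$tad_id <- sprintf("%s:%d-%d", tads$chrom, as.integer(tads$start),
                           as.integer(tads$end))
  }
  out <- stats::setNames(vector("list", nrow(tads)), tads$tad_id)
  out[] <- list(character(0))
  for (ch in unique(tads$chrom)) {
    it <- which(tads$chrom == ch)
    ig <- which(genes$chrom == ch)
    if (!length(ig)) next
    fo <- IRanges::findOverlaps(.as_iranges(tads[it, ]), .as_iranges(genes[ig, ]))
    if (!length(fo)) next
    hits <- split(genes$name[ig][S4Vectors::subjectHits(fo)],
                  tads$tad_id[it[S4Vectors::queryHits(fo)]])
    out[names(hits)] <- lapply(hits, unique)
  }
  out
}
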