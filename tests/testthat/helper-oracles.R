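# Brute-force oracles and tiny fixture builders. These deliberately use the
# most naive algorithm available (per-nucleotide loops, all-pairs scans) and
# never call the package functions they are used to check.

mk_map <- function(chrom, start, end, id = "m", condition = "normal") {
  tad_map(data.frame(chrom = chrom, start = start, end = end), id, condition)
}

# Harrell's concordance by exhaustive pair enumeration: a pair (i, j) with
# t_i < t_j is comparable iff subject i had the event; tied scores score 0.5.
oracle_cindex <- function(score, time, event) {
  num <- den <- 0
  n <- length(score)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (score[i] > score[j]) num <- num + 1
      else if (score[i] == score[j]) num <- num + 0.5
    }
  }
  num / den
}

# UPGMA (average linkage over original distances) by direct O(n^3)
# agglomeration; returns the cophenetic distance matrix.
oracle_upgma_cophenetic <- function(D) {
  labs <- rownames(D)
  clusters <- as.list(seq_along(labs))
  coph <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d <- mean(D[clusters[[a]], clusters[[b]]])
      if (d < bestd) { bestd <- d; best <- c(a, b) }
    }
    ia <- clusters[[best[1]]]; ib <- clusters[[best[2]]]
    coph[ia, ib] <- bestd; coph[ib, ia] <- bestd
    clusters[[best[1]]] <- c(ia, ib)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Per-nucleotide conservation/boundary scores on a small genome: for every
# window, walk the bases (via a base-resolution coverage vector) and the
# boundary coordinates of each map.
oracle_window_scores <- function(maps, weights, chrom_sizes, L, step) {
  lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    starts <- seq(0, size - 1, by = step)
    ends <- pmin(starts + L, size)
    cov <- lapply(maps, function(m) {
      v <- logical(size)
      mm <- m[m$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(mm))) v[(mm$start[r] + 1):mm$end[r]] <- TRUE
      v
    })
    bnds <- lapply(maps, function(m) {
      mm <- m[m$chrom == ch, , drop = FALSE]
      sort(unique(c(mm$start, mm$end)))
    })
    cs <- bs <- numeric(length(starts))
    for (i in seq_along(starts)) {
      a <- starts[i]; b <- ends[i]
      for (k in seq_along(maps)) {
        cs[i] <- cs[i] + weights[k] * mean(cov[[k]][(a + 1):b])
        bs[i] <- bs[i] + weights[k] * any(bnds[[k]] > a & bnds[[k]] < b)
      }
    }
    data.frame(start = starts, end = ends, c = cs, b = bs)
  })
}

# Distinct patients with >= 1 bp overlap per region, by full pairwise scan.
oracle_patient_counts <- function(regions, cnvs) {
  vapply(seq_len(nrow(regions)), function(i) {
    hit <- cnvs$chrom == regions$chrom[i] &
      cnvs$start < regions$end[i] & cnvs$end > regions$start[i]
    length(unique(cnvs$patient_id[hit]))
  }, 0L)
}

# Number of TADs each CNV overlaps, by full pairwise scan.
oracle_cnv_tad_counts <- function(cnvs, tads) {
  vapply(seq_len(nrow(cnvs)), function(i) {
    sum(tads$chrom == cnvs$chrom[i] &
          tads$start < cnvs$end[i] & tads$end > cnvs$start[i])
  }, 0L)
}

# Minimal stand-in for a model_runs object (used to probe the aggregation
# arithmetic with hand-chosen c-indices).
mk_runs <- function(ci, selected) {
  structure(Map(function(c, s) list(ci = c, selected = stats::setNames(rep(1, length(s)), s),
                                    failed = FALSE),
                ci, selected),
            class = "model_runs")
}
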