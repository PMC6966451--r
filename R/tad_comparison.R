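# Best single-partner overlap fractions between two TAD tables.
# For each row of `a`, the largest fraction of it covered by one row of `b`,
# and which row that was (NA when none overlaps).
.best_partner <- function(a, b) {
  frac <- numeric(nrow(a))
  partner <- rep(NA_integer_, nrow(a))
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    if (!length(ib)) next
    fo <- IRanges::findOverlaps(.as_iranges(a[ia, ]), .as_iranges(b[ib, ]))
    if (!length(fo)) next
    qh <- S4Vectors::queryHits(fo); sh <- S4Vectors::subjectHits(fo)
    w <- .overlap_width(a$start[ia][qh], a$end[ia][qh],
                        b$start[ib][sh], b$end[ib][sh]) /
         (a$end[ia][qh] - a$start[ia][qh])
    for (q in unique(qh)) {
      sel <- which(qh == q)
      best <- sel[order(-w[sel], sh[sel])][1]   # ties: leftmost partner
      frac[ia[q]] <- w[best]
      partner[ia[q]] <- ib[sh[best]]
    }
  }
  list(frac = frac, partner = partner)
}

#' Classify normal TADs against a cancer consensus map
#'
#' For each normal TAD, `f_N` is the largest fraction of its sequence
#' covered by a single cancer TAD (its best partner). For that cancer TAD,
#' `f_C` is the largest fraction of *its* sequence covered by a single
#' normal TAD; the pair is reciprocal when that normal TAD is the original
#' one. Normal TADs are labeled constitutive when the relationship is
#' reciprocal and both fractions are at least `c_thresh`; perturbed when
#' `f_N` or `f_C` is at most `p_thresh` (including TADs with no cancer
#' partner at all); ambiguous otherwise. Ambiguous TADs are reported as
#' their own class, never folded into either of the other two.
#'
#' @param normal,cancer consensus TAD tables (`consensus_seg` or plain
#'   data.frames with chrom/start/end; only TAD rows are used).
#' @param c_thresh reciprocal-overlap threshold for constitutive (default
#'   0.95).
#' @param p_thresh maximum-overlap threshold for perturbed (default 0.7).
#' @return data.frame of class `tad_classification`: tad_id, chrom, start,
#'   end, f_N, f_C, reciprocal, label.
#' @export
classify_tads <- function(normal, cancer, c_thresh = 0.95, p_thresh = 0.7) {
  N <- .seg_tads(normal)
  C <- .seg_tads(cancer)
  if (!nrow(N)) stop("no normal TADs to classify")
  fwd <- .best_partner(N, C)
  rev <- .best_partner(C, N)
  f_N <- fwd$frac
  f_C <- ifelse(is.na(fwd$partner), 0, rev$frac[fwd$partner])
  reciprocal <- !is.na(fwd$partner) &
    !is.na(rev$partner[fwd$partner]) &
    rev$partner[fwd$partner] == seq_len(nrow(N))
  label <- rep("ambiguous", nrow(N))
  label[f_N <= p_thresh | f_C <= p_thresh] <- "perturbed"
  label[reciprocal & f_N >= c_thresh & f_C >= c_thresh] <- "constitutive"
  out <- data.frame(tad_id = N$tad_id, chrom = N$chrom, start = N$start,
                    end = N$end, f_N = f_N, f_C = f_C,
                    reciprocal = reciprocal, label = label,
                    cancer_partner = fwd$partner,
                    stringsAsFactors = FALSE)
  structure(out, c_thresh = c_thresh, p_thresh = p_thresh,
            class = c("tad_classification", "data.frame"))
}

.seg_tads <- function(x) {
  df <- as.data.frame(x)
  if ("class" %in% names(df)) df <- df[df$class == "TAD", , drop = FALSE]
  df <- df[, c("chrom", "start", "end")]
  df <- .sort_intervals(df)
  rownames(df) <- NULL
  df$tad_id <- sprintf("%s:%d-%d", df$chrom, as.integer(df$start),
                       as.integer(df$end))
  df
}

#' @export
print.tad_classification <- function(x, ...) {
  tab <- table(factor(x$label, c("constitutive", "perturbed", "ambiguous")))
  cat(sprintf("TAD classification: %d constitutive, %d perturbed, %d ambiguous\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Split and fused subsets of perturbed TADs
#'
#' A perturbed normal TAD is *split* when two or more cancer TADs each lie
#' at least `cover` of their own length inside it — the cancer genome has
#' broken it into pieces. Perturbed normal TADs are *fused* when two or
#' more of them each lie at least `cover` of their own length inside one
#' cancer TAD; fused groups are the connected components induced by the
#' shared covering cancer TAD, and all members of a group must themselves
#' be perturbed. The two subsets are disjoint by construction.
#'
#' @param classification output of [classify_tads()].
#' @param normal,cancer the TAD tables the classification was computed on.
#' @param cover containment fraction (default 0.95).
#' @return List with `split` (character tad_ids) and `fused` (list of
#'   character vectors, one per fused group).
#' @export
detect_split_fused <- function(classification, normal, cancer, cover = 0.95) {
  N <- .seg_tads(normal)
  C <- .seg_tads(cancer)
  stopifnot(nrow(N) == nrow(classification))
  perturbed <- classification$label == "perturbed"

  # fraction of each cancer TAD contained in each overlapping normal TAD
  split_ids <- character(0)
  fused_groups <- list()
  if (nrow(C)) {
    cont_n <- vector("list", nrow(N))   # cancer TADs >= cover inside normal i
    cont_c <- vector("list", nrow(C))   # normal TADs >= cover inside cancer j
    for (ch in unique(N$chrom)) {
      iN <- which(N$chrom == ch); iC <- which(C$chrom == ch)
      if (!length(iC)) next
      fo <- IRanges::findOverlaps(.as_iranges(N[iN, ]), .as_iranges(C[iC, ]))
      qh <- S4Vectors::queryHits(fo); sh <- S4Vectors::subjectHits(fo)
      ow <- .overlap_width(N$start[iN][qh], N$end[iN][qh],
                           C$start[iC][sh], C$end[iC][sh])
      inN <- ow / (C$end[iC][sh] - C$start[iC][sh]) >= cover
      inC <- ow / (N$end[iN][qh] - N$start[iN][qh]) >= cover
      for (k in which(inN)) {
        cont_n[[iN[qh[k]]]] <- c(cont_n[[iN[qh[k]]]], iC[sh[k]])
      }
      for (k in which(inC)) {
        cont_c[[iC[sh[k]]]] <- c(cont_c[[iC[sh[k]]]], iN[qh[k]])
      }
    }
    split_ids <- N$tad_id[perturbed & lengths(cont_n) >= 2]
    for (j in seq_len(nrow(C))) {
      members <- cont_c[[j]]
      if (length(members) >= 2 && all(perturbed[members])) {
        fused_groups[[length(fused_groups) + 1]] <- N$tad_id[sort(members)]
      }
    }
  }
  list(split = split_ids, fused = fused_groups)
}

# Integral of interval coverage over [qa, qb), one query at a time but
# vectorized over signal intervals. `s`,`e` need not be disjoint (coverage
# stacks); divide by (qb - qa) for the mean per-base coverage.
.coverage_integral <- function(s, e, qa, qb) {
  if (!length(s)) return(numeric(length(qa)))
  vapply(seq_along(qa), function(i) {
    sum(pmax(0, pmin(e, qb[i]) - pmax(s, qa[i])))
  }, 0)
}

# Per-id merged signal intervals on one chromosome, so that coverage counts
# distinct ids (e.g. patients) per base rather than raw segments.
.stack_by_id <- function(signal, ch) {
  i <- which(signal$chrom == ch)
  if (!length(i)) return(list(start = numeric(0), end = numeric(0)))
  if (is.null(signal$id)) {
    return(list(start = signal$start[i], end = signal$end[i]))
  }
  parts <- lapply(split(i, signal$id[i]), function(ii) {
    .merge_intervals(signal$start[ii], signal$end[ii])
  })
  list(start = unlist(lapply(parts, `[[`, "start"), use.names = FALSE),
       end = unlist(lapply(parts, `[[`, "end"), use.names = FALSE))
}

#' Scaled-region meta-profile of interval coverage
#'
#' Computes the classic scale-regions profile: each region's body is
#' linearly rescaled to `body` bp and flanked by unscaled `flank`-bp
#' margins; within each `bin`-bp bin the signal is the mean per-base
#' coverage of the signal intervals, and bins are aggregated across regions
#' with the median (or mean). When the signal table carries an `id` column
#' (e.g. patient ids for CNV segments), each id's intervals are merged
#' first so the coverage counts distinct ids per base.
#'
#' @param regions data.frame (chrom, start, end) of regions (e.g. a TAD
#'   class); regions shorter than two bins are skipped with a warning.
#' @param signal data.frame (chrom, start, end\[, id\]) of signal intervals.
#' @param body target body length in bp (default 2e6).
#' @param flank flank length in bp (default 1e6).
#' @param bin bin width in bp (default 1e4).
#' @param agg `"median"` (default) or `"mean"` aggregation across regions.
#' @return data.frame of class `meta_profile`: bin index, position_class
#'   (flank5/body/flank3), offset (bp from region start, flank negative),
#'   value.
#' @export
scaled_profile <- function(regions, signal, body = 2e6, flank = 1e6,
                           bin = 1e4, agg = c("median", "mean")) {
  agg <- match.arg(agg)
  if (!nrow(regions)) stop("no regions")
  short <- (regions$end - regions$start) < 2 * bin
  if (any(short)) {
    warning(sprintf("skipping %d region(s) shorter than two bins", sum(short)))
    regions <- regions[!short, , drop = FALSE]
    if (!nrow(regions)) stop("no usable regions")
  }
  nb_fl <- as.integer(flank / bin)
  nb_bd <- as.integer(body / bin)
  prof <- matrix(NA_real_, nrow(regions), 2 * nb_fl + nb_bd)
  for (r in seq_len(nrow(regions))) {
    sig <- .stack_by_id(signal, regions$chrom[r])
    s0 <- regions$start[r]; e0 <- regions$end[r]
    up_qa <- s0 - flank + bin * (seq_len(nb_fl) - 1)
    up_qb <- up_qa + bin
    dn_qa <- e0 + bin * (seq_len(nb_fl) - 1)
    dn_qb <- dn_qa + bin
    # body bins in original coordinates: equal slices of the region
    bd_edges <- s0 + (e0 - s0) * (0:nb_bd) / nb_bd
    bd_qa <- bd_edges[-(nb_bd + 1)]
    bd_qb <- bd_edges[-1]
    vals <- c(.coverage_integral(sig$start, sig$end, up_qa, up_qb) / bin,
              .coverage_integral(sig$start, sig$end, bd_qa, bd_qb) / (bd_qb - bd_qa),
              .coverage_integral(sig$start, sig$end, dn_qa, dn_qb) / bin)
    prof[r, ] <- vals
  }
  value <- apply(prof, 2, if (agg == "median") stats::median else mean)
  out <- data.frame(
    bin = seq_len(ncol(prof)),
    position_class = rep(c("flank5", "body", "flank3"), c(nb_fl, nb_bd, nb_fl)),
    offset = c(-flank + bin * (seq_len(nb_fl) - 1),
               body * (seq_len(nb_bd) - 1) / nb_bd,
               body + bin * (seq_len(nb_fl) - 1)),
    value = value
  )
  structure(out, body = body, flank = flank, bin = bin, agg = agg,
            n_regions = nrow(regions),
            class = c("meta_profile", "data.frame"))
}

#' Reference-point meta-profile around centers
#'
#' Computes feature density in fixed-width bins around each center (e.g.
#' TBR midpoints): per bin, the mean per-base coverage of the feature
#' intervals, averaged across centers. Bins with no data count as zero.
#'
#' @param centers data.frame (chrom, start, end); the midpoint of each
#'   interval is the reference point.
#' @param features data.frame (chrom, start, end) of features (CTCF peaks,
#'   TSSs, ...).
#' @param flank half-window around each center in bp (default 2e5).
#' @param bin bin width in bp (default 5e3).
#' @param agg `"mean"` (default) or `"median"` aggregation across centers.
#' @return data.frame of class `meta_profile`: bin, offset (bp relative to
#'   center), value.
#' @export
reference_point_profile <- function(centers, features, flank = 2e5,
                                    bin = 5e3, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  if (!nrow(centers)) stop("no centers")
  nb <- as.integer(2 * flank / bin)
  prof <- matrix(0, nrow(centers), nb)
  mids <- floor((centers$start + centers$end) / 2)
  for (r in seq_len(nrow(centers))) {
    sig <- .stack_by_id(features, centers$chrom[r])
    qa <- mids[r] - flank + bin * (seq_len(nb) - 1)
    prof[r, ] <- .coverage_integral(sig$start, sig$end, qa, qa + bin) / bin
  }
  out <- data.frame(
    bin = seq_len(nb),
    offset = -flank + bin * (seq_len(nb) - 1) + bin / 2,
    value = apply(prof, 2, if (agg == "median") stats::median else mean)
  )
  structure(out, flank = flank, bin = bin, agg = agg,
            n_regions = nrow(centers),
            class = c("meta_profile", "data.frame"))
}

#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(x$bin, x$value, type = "l", xlab = "bin",
                 ylab = sprintf("%s coverage", attr(x, "agg")), ...)
  if (!is.null(x$position_class)) {
    at <- range(which(x$position_class == "body"))
    graphics::abline(v = at + c(-0.5, 0.5), lty = 2, col = "grey50")
  }
  invisible(x)
}
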