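#' Asymmetric similarity between two TAD maps
#'
#' For every TAD in `A`, finds the single TAD in `B` covering the largest
#' fraction of it (0 if none overlaps) and returns the median of these
#' fractions over all TADs in `A`. The measure is deliberately asymmetric:
#' `map_similarity(A, B)` asks how well B's domains explain A's.
#'
#' @param A,B `tad_map` objects on the same assembly.
#' @return Similarity score in \[0, 1\].
#' @export
map_similarity <- function(A, B) {
  if (!nrow(A)) stop("map A has no TADs; similarity undefined")
  fractions <- numeric(nrow(A))
  for (ch in unique(A$chrom)) {
    ia <- which(A$chrom == ch)
    ib <- which(B$chrom == ch)
    if (!length(ib)) next
    fo <- IRanges::findOverlaps(.as_iranges(A[ia, ]), .as_iranges(B[ib, ]))
    if (!length(fo)) next
    qh <- S4Vectors::queryHits(fo)
    sh <- S4Vectors::subjectHits(fo)
    w <- .overlap_width(A$start[ia][qh], A$end[ia][qh],
                        B$start[ib][sh], B$end[ib][sh]) /
         (A$end[ia][qh] - A$start[ia][qh])
    best <- tapply(w, qh, max)
    fractions[ia[as.integer(names(best))]] <- as.numeric(best)
  }
  stats::median(fractions)
}

#' Pairwise similarity matrix for a list of TAD maps
#'
#' @param maps list of `tad_map` objects.
#' @return Square matrix; entry (i, j) is `map_similarity(maps[[i]], maps[[j]])`.
#' @export
map_similarity_matrix <- function(maps) {
  ids <- vapply(maps, attr, "", "sample_id")
  n <- length(maps)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) m[i, j] <- map_similarity(maps[[i]], maps[[j]])
  }
  m
}

#' Windowed TAD conservation and boundary scores
#'
#' Slides windows of length `L` (stepped by `step`) along each chromosome
#' and computes, per window i: the conservation score `c_i` = the weighted
#' average (over maps) of the fraction of the window's nucleotides lying
#' inside a TAD, and the boundary score `b_i` = the summed weight of the
#' maps with at least one TAD boundary strictly inside the window. Both
#' scores lie in \[0, 1\]. Windows start at position 0; windows reaching past
#' the chromosome end are truncated and scored over their actual length. A
#' boundary coordinate p counts as inside window \[a, b) when a < p < b, so
#' a window flush against a TAD edge does not see that edge as a boundary.
#'
#' @param maps list of `tad_map` objects sharing one assembly.
#' @param weights per-map weights (same order as `maps`) summing to 1; see
#'   [assign_map_weights()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @param L window length in bp (default 40000).
#' @param step window shift in bp (default 1000); must not exceed `L`.
#' @return A `score_track`: per-chromosome data.frames with columns
#'   start, end, c, b; attributes `L` and `step`.
#' @export
window_scores <- function(maps, weights, chrom_sizes, L = 40000, step = 1000) {
  if (step > L) stop("step must not exceed window length L")
  if (length(weights) != length(maps)) stop("one weight per map required")
  if (abs(sum(weights) - 1) > 1e-6) stop("map weights must sum to 1")
  track <- lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    starts <- seq(0, size - 1, by = step)
    ends <- pmin(starts + L, size)
    cw <- numeric(length(starts))
    bw <- numeric(length(starts))
    for (k in seq_along(maps)) {
      m <- maps[[k]]
      i <- which(m$chrom == ch)
      cov <- .covered_in_window(m$start[i], m$end[i], starts, ends)
      cw <- cw + weights[k] * cov / (ends - starts)
      bnd <- sort(unique(c(m$start[i], m$end[i])))
      # boundaries strictly inside [a, b): integer p with a < p <= b - 1
      nb <- findInterval(ends - 1, bnd) - findInterval(starts, bnd)
      bw <- bw + weights[k] * (nb > 0)
    }
    data.frame(start = starts, end = ends, c = cw, b = bw)
  })
  names(track) <- names(chrom_sizes)
  structure(track, L = L, step = step, class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("score_track: %d chromosome(s), L=%d, step=%d, %d windows\n",
              length(x), attr(x, "L"), attr(x, "step"),
              sum(vapply(x, nrow, 0L))))
  invisible(x)
}

#' Overlap fraction of consecutive sliding windows
#'
#' Consecutive windows of length `L` shifted by `step` share `(L - step) / L`
#' of their sequence (0.975 for the default 40-kb windows stepped by 1 kb).
#'
#' @param L window length in bp.
#' @param step window shift in bp.
#' @return Fraction in \[0, 1).
#' @export
window_overlap_fraction <- function(L = 40000, step = 1000) {
  if (step > L) stop("step must not exceed window length L")
  (L - step) / L
}

# Greedy merge of one chromosome's windows into maximal runs.
# Returns data.frame(start, end) of run spans.
.merge_runs <- function(start, end, cs, bs, c_star, b_star, average) {
  runs_s <- numeric(0); runs_e <- numeric(0)
  cur_first <- NA_real_; cur_last <- NA_real_
  cur_sum <- 0; cur_n <- 0L
  flush <- function() {
    if (!is.na(cur_first)) {
      runs_s <<- c(runs_s, cur_first)
      runs_e <<- c(runs_e, cur_last)
    }
    cur_first <<- NA_real_; cur_sum <<- 0; cur_n <<- 0L
  }
  for (j in seq_along(start)) {
    if (bs[j] >= b_star) { flush(); next }
    ok <- if (average == "run" && cur_n > 0L) {
      (cur_sum + cs[j]) / (cur_n + 1L) >= c_star
    } else {
      cs[j] >= c_star
    }
    if (ok) {
      if (is.na(cur_first)) cur_first <- start[j]
      cur_last <- end[j]
      cur_sum <- cur_sum + cs[j]
      cur_n <- cur_n + 1L
    } else {
      flush()
      if (cs[j] >= c_star) {        # window can seed a fresh run
        cur_first <- start[j]; cur_last <- end[j]
        cur_sum <- cs[j]; cur_n <- 1L
      }
    }
  }
  flush()
  data.frame(start = runs_s, end = runs_e)
}

#' Build a consensus segmentation from a score track
#'
#' Merges adjacent windows into maximal runs as long as (1) the running
#' average conservation score stays at or above `c_star` and (2) no window
#' in the run has a boundary score of `b_star` or more (such windows
#' terminate a run and belong to none). Runs spanning at least `min_tad`
#' bases become consensus TADs. Each region between consecutive TADs —
#' including chromosome-terminal stretches — is labeled a topological
#' boundary region (TBR) when its length is at most `tbr_max`, and a
#' disorganized chromatin region otherwise.
#'
#' @param track a `score_track` from [window_scores()].
#' @param c_star conservation threshold (default 0.5).
#' @param b_star boundary-score threshold (default 0.5).
#' @param min_tad minimum consensus TAD size in bp (default 40000).
#' @param tbr_max maximum TBR length in bp (default 400000).
#' @param average `"run"` applies the conservation threshold to the running
#'   mean over the merged run (default); `"window"` applies it to each
#'   window separately.
#' @return A `consensus_seg`: data.frame (chrom, start, end, class) with
#'   class in TAD/TBR/disorganized, plus the thresholds as attributes.
#' @export
build_consensus <- function(track, c_star = 0.5, b_star = 0.5,
                            min_tad = 40000, tbr_max = 400000,
                            average = c("run", "window")) {
  average <- match.arg(average)
  pieces <- lapply(names(track), function(ch) {
    win <- track[[ch]]
    chrom_len <- max(win$end)
    runs <- .merge_runs(win$start, win$end, win$c, win$b, c_star, b_star, average)
    # a run's trailing window may reach past the next run's start on noisy
    # tracks; clip so regions never overlap, and re-apply the size filter
    # until stable (clipping can push a run below min_tad)
    repeat {
      runs <- runs[runs$end - runs$start >= min_tad, , drop = FALSE]
      if (nrow(runs) < 2) break
      clipped <- pmin(runs$end[-nrow(runs)], runs$start[-1])
      if (all(clipped == runs$end[-nrow(runs)])) break
      runs$end[-nrow(runs)] <- clipped
    }
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), class = character(0))
    gap <- function(a, b) {
      if (b <= a) return(NULL)
      data.frame(chrom = ch, start = a, end = b,
                 class = if (b - a <= tbr_max) "TBR" else "disorganized")
    }
    if (!nrow(runs)) {
      return(rbind(out, gap(0, chrom_len)))
    }
    out <- rbind(out, gap(0, runs$start[1]))
    for (i in seq_len(nrow(runs))) {
      out <- rbind(out, data.frame(chrom = ch, start = runs$start[i],
                                   end = runs$end[i], class = "TAD"))
      nxt <- if (i < nrow(runs)) runs$start[i + 1] else chrom_len
      out <- rbind(out, gap(runs$end[i], nxt))
    }
    out
  })
  seg <- do.call(rbind, pieces)
  rownames(seg) <- NULL
  structure(seg, c_star = c_star, b_star = b_star, min_tad = min_tad,
            tbr_max = tbr_max, average = average,
            class = c("consensus_seg", "data.frame"))
}

#' @export
print.consensus_seg <- function(x, ...) {
  tab <- table(x$class)
  cat("consensus segmentation:",
      paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Extract the consensus TADs from a segmentation
#'
#' @param seg a `consensus_seg`.
#' @return data.frame (chrom, start, end) of TAD regions, with a `tad_id`
#'   column of the form `chrom:start-end`.
#' @export
consensus_tads <- function(seg) {
  t <- as.data.frame(seg)[seg$class == "TAD", c("chrom", "start", "end")]
  rownames(t) <- NULL
  t$tad_id <- sprintf("%s:%d-%d", t$chrom, as.integer(t$start), as.integer(t$end))
  t
}

#' Write a consensus segmentation as BED4
#'
#' The fourth column carries the region class (TAD, TBR, disorganized).
#'
#' @param seg a `consensus_seg`.
#' @param path output path.
#' @export
write_consensus <- function(seg, path) {
  df <- data.frame(seg$chrom,
                   format(seg$start, scientific = FALSE, trim = TRUE),
                   format(seg$end, scientific = FALSE, trim = TRUE),
                   seg$class)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
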