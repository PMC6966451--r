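# Internal interval arithmetic. All coordinates in this package are 0-based,
# half-open [start, end); IRanges (1-based, closed) is used only transiently
# for overlap queries.

.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

# Overlap width between interval pairs (half-open coordinates); 0 if disjoint.
.overlap_width <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

.check_interval_frame <- function(df, what = "interval table") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop(what, " must have columns chrom, start, end", call. = FALSE)
  }
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    stop(what, ": start/end must be numeric", call. = FALSE)
  }
  if (any(df$start < 0)) stop(what, ": negative start coordinate", call. = FALSE)
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop(what, ": empty or inverted interval at row ", bad[1], call. = FALSE)
  }
  invisible(df)
}

.sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# Requires sorted input; returns index of first offending row or 0L.
.first_overlap_row <- function(df) {
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    if (length(i) < 2) next
    s <- df$start[i]; e <- df$end[i]
    j <- which(s[-1] < e[-length(e)])
    if (length(j)) return(i[j[1] + 1L])
  }
  0L
}

# Cumulative covered length C(x) for a set of *disjoint, sorted* intervals on
# one chromosome: number of covered bases in [0, x). Vectorized in x.
.cum_covered <- function(s, e, x) {
  if (!length(s)) return(numeric(length(x)))
  cl <- cumsum(e - s)
  k <- findInterval(x, s)
  out <- numeric(length(x))
  pos <- k > 0
  kk <- k[pos]
  out[pos] <- cl[kk] - pmax(0, e[kk] - x[pos])
  out
}

# Covered bases of disjoint sorted intervals within each query [qa, qb).
.covered_in_window <- function(s, e, qa, qb) {
  .cum_covered(s, e, qb) - .cum_covered(s, e, qa)
}

# Merge possibly-overlapping intervals on one chromosome into disjoint ones.
.merge_intervals <- function(s, e) {
  if (!length(s)) return(list(start = numeric(0), end = numeric(0)))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  outs <- numeric(0); oute <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- s[i]; me <- e[i]
    }
  }
  list(start = c(outs, ms), end = c(oute, me))
}
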