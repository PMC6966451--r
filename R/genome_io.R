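#' Construct a TAD map
#'
#' A TAD map is a set of non-overlapping genomic intervals (0-based,
#' half-open) annotated with the tissue/cell line it was derived from and
#' whether that sample is normal or cancer. Intervals are validated and
#' sorted by (chrom, start).
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @param sample_id tissue/cell-line label.
#' @param condition `"normal"` or `"cancer"`.
#' @param chrom_sizes optional named vector of chromosome lengths; intervals
#'   on chromosomes absent from it are dropped with a warning, and intervals
#'   exceeding the chromosome length raise an error.
#' @return A `tad_map`: a data.frame of intervals with attributes
#'   `sample_id` and `condition`.
#' @export
tad_map <- function(intervals, sample_id, condition = c("normal", "cancer"),
                    chrom_sizes = NULL) {
  condition <- match.arg(condition)
  df <- as.data.frame(intervals)[, c("chrom", "start", "end")]
  df$chrom <- as.character(df$chrom)
  .check_interval_frame(df, sprintf("TAD map '%s'", sample_id))
  if (!is.null(chrom_sizes)) {
    unknown <- !(df$chrom %in% names(chrom_sizes))
    if (any(unknown)) {
      warning(sprintf("TAD map '%s': dropping %d interval(s) on chromosomes absent from chrom_sizes (%s)",
                      sample_id, sum(unknown),
                      paste(unique(df$chrom[unknown]), collapse = ", ")))
      df <- df[!unknown, , drop = FALSE]
    }
    over <- df$end > unname(chrom_sizes[df$chrom])
    if (any(over)) {
      stop(sprintf("TAD map '%s': interval end exceeds chromosome length at row %d",
                   sample_id, which(over)[1]))
    }
  }
  df <- .sort_intervals(df)
  bad <- .first_overlap_row(df)
  if (bad > 0) {
    stop(sprintf("TAD map '%s': overlapping intervals (row %d overlaps its predecessor on %s)",
                 sample_id, bad, df$chrom[bad]))
  }
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, condition = condition,
            class = c("tad_map", "data.frame"))
}

#' @export
print.tad_map <- function(x, ...) {
  cat(sprintf("TAD map '%s' (%s): %d TADs on %d chromosome(s)\n",
              attr(x, "sample_id"), attr(x, "condition"),
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Read a TAD map from a BED-like file
#'
#' Accepts whitespace/tab-separated files with at least three columns
#' (chrom, start, end). Two coordinate dialects are supported: `"bed"`
#' (0-based half-open, kept as-is) and `"inclusive"` (0-based start with
#' inclusive end, e.g. `chr9 21240000 24400999`; converted to half-open by
#' `end + 1`).
#'
#' @param path file path.
#' @param sample_id,condition,chrom_sizes passed to [tad_map()].
#' @param dialect `"bed"` or `"inclusive"`.
#' @return A `tad_map`.
#' @export
read_tad_map <- function(path, sample_id, condition = c("normal", "cancer"),
                         dialect = c("bed", "inclusive"), chrom_sizes = NULL) {
  dialect <- match.arg(dialect)
  condition <- match.arg(condition)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines)) {
    return(tad_map(data.frame(chrom = character(0), start = numeric(0),
                              end = numeric(0)),
                   sample_id, condition, chrom_sizes))
  }
  fields <- strsplit(lines, "[ \t]+")
  n <- lengths(fields)
  if (any(n < 3)) {
    stop(sprintf("%s: line %d has fewer than 3 fields", path, which(n < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric coordinates at line %d", path, bad[1]))
  }
  if (dialect == "inclusive") end <- end + 1
  tad_map(data.frame(chrom = chrom, start = start, end = end),
          sample_id, condition, chrom_sizes)
}

#' Write a TAD map (round-trips with [read_tad_map()])
#'
#' @param map a `tad_map`.
#' @param path output path.
#' @param dialect `"bed"` writes half-open coordinates unchanged;
#'   `"inclusive"` writes `end - 1`.
#' @export
write_tad_map <- function(map, path, dialect = c("bed", "inclusive")) {
  dialect <- match.arg(dialect)
  end <- if (dialect == "inclusive") map$end - 1 else map$end
  df <- data.frame(chrom = map$chrom, start = format(map$start, scientific = FALSE, trim = TRUE),
                   end = format(end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path tab-separated file: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  if (anyDuplicated(df$chrom)) stop(path, ": duplicated chromosome name")
  if (any(df$size <= 0)) stop(path, ": non-positive chromosome length")
  stats::setNames(df$size, df$chrom)
}

#' Read somatic copy-number segments (SEG-style table)
#'
#' Expects columns sample, chromosome, start, end, num_probes, segment_mean
#' (a header line is tolerated). Coordinates are normalized to 0-based
#' half-open; the default dialect `"seg"` treats input as 1-based with
#' inclusive ends (the TCGA SEG convention). The patient identifier is the
#' sample string truncated to `barcode_nchar` characters (TCGA-style
#' aliquot barcodes collapse to the first 12); shorter strings are kept
#' unchanged. The gain/loss sign is derived from the segment mean.
#'
#' @param path file path.
#' @param cancer_type cohort label attached to every segment.
#' @param dialect `"seg"` (1-based inclusive) or `"bed"` (0-based half-open).
#' @param barcode_nchar truncation length for the sample barcode.
#' @return data.frame of class `cnv_segments`: patient_id, cancer_type,
#'   chrom, start, end, num_probes, segment_mean, sign.
#' @export
read_seg_file <- function(path, cancer_type = NA_character_,
                          dialect = c("seg", "bed"), barcode_nchar = 12L) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 6) stop(path, ": SEG file needs 6 columns")
  df <- df[, 1:6]
  names(df) <- c("sample", "chrom", "start", "end", "num_probes", "segment_mean")
  # tolerate a single header row
  if (is.na(suppressWarnings(as.numeric(df$start[1])))) df <- df[-1, , drop = FALSE]
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop(sprintf("%s: non-numeric %s at data row %d", path, what, which(is.na(v))[1]))
    }
    v
  }
  out <- data.frame(
    patient_id = substr(df$sample, 1L, barcode_nchar),
    cancer_type = cancer_type,
    chrom = df$chrom,
    start = num("start", "start"),
    end = num("end", "end"),
    num_probes = num("num_probes", "num_probes"),
    segment_mean = num("segment_mean", "segment_mean"),
    stringsAsFactors = FALSE
  )
  if (dialect == "seg") out$start <- out$start - 1
  if (any(out$num_probes < 1)) stop(path, ": num_probes < 1")
  .check_interval_frame(out, "CNV segments")
  out$sign <- ifelse(out$segment_mean > 0, "gain", "loss")
  class(out) <- c("cnv_segments", "data.frame")
  out
}

#' Read a clinical table with survival endpoints
#'
#' Tab-separated with header columns patient_id, cancer_type, days,
#' vital_status, age, sex. Overall survival time is days to death or to the
#' last follow-up; the event indicator is 1 when the vital status denotes
#' death. Rows with missing time or status are dropped with a warning.
#'
#' @param path file path.
#' @return data.frame: patient_id, cancer_type, time, event, age, sex.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "cancer_type", "days", "vital_status", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  days <- suppressWarnings(as.numeric(df$days))
  status <- tolower(trimws(as.character(df$vital_status)))
  drop <- is.na(days) | is.na(status) | !nzchar(status)
  if (any(drop)) {
    warning(sprintf("%s: dropped %d record(s) with missing survival time or status",
                    path, sum(drop)))
    df <- df[!drop, , drop = FALSE]
    days <- days[!drop]; status <- status[!drop]
  }
  if (anyDuplicated(df$patient_id)) {
    stop(path, ": duplicated patient_id ", df$patient_id[anyDuplicated(df$patient_id)])
  }
  if (any(days < 0)) stop(path, ": negative survival time")
  data.frame(
    patient_id = df$patient_id,
    cancer_type = df$cancer_type,
    time = days,
    event = as.integer(status %in% c("dead", "deceased", "1")),
    age = as.numeric(df$age),
    sex = tolower(df$sex),
    stringsAsFactors = FALSE
  )
}

#' Read a BED file of features (genes, peaks)
#'
#' @param path BED3(+name) file, 0-based half-open.
#' @return data.frame: chrom, start, end, name (name synthesized if absent).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop(path, ": BED needs >= 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]),
                    name = if (ncol(df) >= 4) as.character(df[[4]])
                           else sprintf("feature_%d", seq_len(nrow(df))),
                    stringsAsFactors = FALSE)
  .check_interval_frame(out, "BED")
  .sort_intervals(out)
}

#' Summarize TAD maps: counts, median sizes, median of medians
#'
#' Computes per-map TAD counts and median TAD sizes (end - start), and the
#' median of the per-map medians within each condition.
#'
#' @param maps list of `tad_map` objects.
#' @return list with `per_map` (sample_id, condition, n_tads, median_size)
#'   and `by_condition` (condition, median_of_medians).
#' @export
tad_map_summary <- function(maps) {
  if (!length(maps)) stop("need at least one TAD map")
  per_map <- do.call(rbind, lapply(maps, function(m) {
    data.frame(sample_id = attr(m, "sample_id"),
               condition = attr(m, "condition"),
               n_tads = nrow(m),
               median_size = if (nrow(m)) stats::median(m$end - m$start) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_map) <- NULL
  by_condition <- stats::aggregate(median_size ~ condition, data = per_map,
                                   FUN = stats::median)
  names(by_condition)[2] <- "median_of_medians"
  list(per_map = per_map, by_condition = by_condition)
}
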