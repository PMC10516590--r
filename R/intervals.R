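#' Genomic interval tables
#'
#' Intervals throughout the package are plain data frames with columns
#' `chrom`, `start`, `end` in 0-based half-open coordinates (the native
#' convention of the chain and BED formats, so no shifting is ever needed
#' on input or output). Optional `name`, `score`, `strand` columns are
#' carried along untouched.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open coordinates; `start < end` elementwise.
#' @param ... further equal-length columns (e.g. `name`, `score`, `strand`).
#' @return a data frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop("invalid interval(s): start >= end at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(df$start < 0)) stop("negative interval start")
  invisible(df)
}

# data frame (0-based half-open) -> IRangesList keyed by chromosome
.iv_split_ir <- function(df) {
  if (nrow(df) == 0) return(IRanges::IRangesList())
  ir <- IRanges::IRanges(start = df$start + 1, end = df$end)
  S4Vectors::split(ir, factor(df$chrom, levels = unique(df$chrom)))
}

# IRangesList -> data frame
.irl_to_df <- function(irl) {
  if (length(irl) == 0)
    return(genomic_intervals())
  chroms <- rep(names(irl), lengths(irl))
  ir <- unlist(irl, use.names = FALSE)
  out <- data.frame(chrom = chroms, start = IRanges::start(ir) - 1,
                    end = IRanges::end(ir), stringsAsFactors = FALSE)
  out <- out[out$start < out$end, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Merge nearby intervals
#'
#' Collapses intervals on the same chromosome whose separation
#' (`start_next - end_prev`) is at most `max_dist`. Touching intervals
#' (distance 0) therefore always merge. The operation is idempotent and
#' insensitive to input order.
#'
#' @param intervals interval data frame (`chrom`, `start`, `end`).
#' @param max_dist non-negative integer; maximum separation that still merges.
#' @return merged, sorted interval data frame.
#' @examples
#' merge_intervals(data.frame(chrom = "c", start = c(0, 25, 60),
#'                            end = c(10, 35, 70)), max_dist = 20)
#' @export
merge_intervals <- function(intervals, max_dist = 0) {
  stopifnot(max_dist >= 0)
  validate_intervals(intervals)
  if (nrow(intervals) == 0) return(genomic_intervals())
  irl <- .iv_split_ir(intervals)
  merged <- IRanges::reduce(irl, min.gapwidth = max_dist + 1)
  .irl_to_df(merged)
}

#' Per-base species coverage thresholding
#'
#' Given one (flattened) interval track per species, returns the maximal
#' intervals where the number of species covering a base is at least
#' `min_species`, keeping only pieces of length at least `min_span`.
#'
#' @param tracks named list of interval data frames, one per species.
#' @param min_species minimum per-base species count.
#' @param min_span minimum output interval length in bp.
#' @return interval data frame of the qualifying regions.
#' @export
coverage_count <- function(tracks, min_species, min_span = 1) {
  stopifnot(is.list(tracks), min_species >= 1, min_span >= 1)
  if (min_species > length(tracks)) {
    warning("min_species exceeds the number of tracks; returning no intervals")
    return(genomic_intervals())
  }
  flat <- lapply(tracks, function(t) merge_intervals(t, max_dist = 0))
  flat <- flat[vapply(flat, nrow, 0L) > 0]
  if (length(flat) == 0) return(genomic_intervals())
  all_df <- do.call(rbind, lapply(flat, function(d) d[c("chrom", "start", "end")]))
  chroms <- unique(all_df$chrom)
  pieces <- lapply(chroms, function(ch) {
    sub <- all_df[all_df$chrom == ch, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(sub$start + 1, sub$end))
    hits <- IRanges::slice(cov, lower = min_species, rangesOnly = TRUE)
    if (length(hits) == 0) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(hits) - 1,
               end = IRanges::end(hits), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0) return(genomic_intervals())
  out <- out[out$end - out$start >= min_span, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Intersect two interval sets
#'
#' @param a,b interval data frames.
#' @return interval data frame of the per-chromosome intersection.
#' @export
intersect_intervals <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(genomic_intervals())
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  pieces <- lapply(chroms, function(ch) {
    ia <- a[a$chrom == ch, ]; ib <- b[b$chrom == ch, ]
    ra <- IRanges::reduce(IRanges::IRanges(ia$start + 1, ia$end))
    rb <- IRanges::reduce(IRanges::IRanges(ib$start + 1, ib$end))
    ri <- IRanges::intersect(ra, rb)
    if (length(ri) == 0) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ri) - 1,
               end = IRanges::end(ri), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(genomic_intervals())
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

# clip intervals to a single window (chrom, start, end), dropping empties
clip_intervals <- function(intervals, window) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) return(genomic_intervals())
  sub <- intervals[intervals$chrom == window$chrom, , drop = FALSE]
  if (nrow(sub) == 0) return(genomic_intervals())
  sub$start <- pmax(sub$start, window$start)
  sub$end <- pmin(sub$end, window$end)
  sub <- sub[sub$start < sub$end, , drop = FALSE]
  rownames(sub) <- NULL
  class(sub) <- c("genomic_intervals", "data.frame")
  sub
}

# total bases covered by the union of an interval set
interval_union_width <- function(intervals) {
  m <- merge_intervals(intervals, 0)
  if (nrow(m) == 0) return(0)
  sum(m$end - m$start)
}

# TRUE for each row of `a` overlapping any row of `b` (same chrom, >=1 bp)
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  res <- rep(FALSE, nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(bb) == 0) next
    qa <- IRanges::IRanges(a$start[ai] + 1, a$end[ai])
    sb <- IRanges::IRanges(bb$start + 1, bb$end)
    res[ai] <- IRanges::overlapsAny(qa, sb)
  }
  res
}
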