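#' Construct a table of genomic intervals
#'
#' Intervals are strandless, BED-style: 0-based starts, half-open ends
#' (`[start, end)`). This is the coordinate convention used throughout the
#' package; all readers and writers respect it.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based inclusive start positions.
#' @param end Integer vector of 0-based exclusive end positions.
#' @param id Optional character vector of stable region labels. Defaults to
#'   `chrom:start-end`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `id`, sorted
#'   by `(chrom, start, end)`.
#' @examples
#' g_intervals("chr1", 1000, 1200)
#' @export
g_intervals <- function(chrom, start, end, id = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n)
  if (n > 0) {
    if (any(is.na(chrom)) || any(!nzchar(chrom)))
      stop("chromosome names must be non-empty")
    if (any(is.na(start)) || any(is.na(end)))
      stop("interval coordinates must be finite")
    if (any(start < 0L)) stop("start must be >= 0")
    if (any(end <= start)) stop("end must be > start (half-open intervals)")
  }
  if (is.null(id)) id <- sprintf("%s:%d-%d", chrom, start, end)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   id = as.character(id), stringsAsFactors = FALSE)
  sort_intervals(df)
}

#' Sort an interval table by (chrom, start, end)
#'
#' @param xs Interval `data.frame` as returned by [g_intervals()].
#' @return The same table, sorted, with row names dropped.
#' @export
sort_intervals <- function(xs) {
  xs <- xs[order(xs$chrom, xs$start, xs$end), , drop = FALSE]
  rownames(xs) <- NULL
  xs
}

#' Test whether an interval table is sorted
#'
#' @param xs Interval `data.frame`.
#' @return Logical scalar.
#' @export
is_sorted_intervals <- function(xs) {
  if (nrow(xs) < 2) return(TRUE)
  !is.unsorted(order(xs$chrom, xs$start, xs$end))
}

# Internal: interval data.frame (0-based half-open) -> GRanges (1-based closed)
intervals_to_granges <- function(xs) {
  GenomicRanges::GRanges(
    seqnames = xs$chrom,
    ranges = IRanges::IRanges(start = xs$start + 1L, end = xs$end)
  )
}

granges_to_intervals <- function(gr, id = NULL) {
  g_intervals(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    id = id
  )
}

# maxgap encoding of the windowed-overlap rule: two half-open intervals
# window-overlap iff their gap is strictly less than w, i.e. maxgap = w - 1
# in IRanges terms (w = 0 reduces to true overlap, maxgap = -1).
window_maxgap <- function(w) {
  w <- as.integer(w)
  if (is.na(w) || w < 0L) stop("window size w must be a non-negative integer")
  w - 1L
}

#' Windowed overlap of two single intervals
#'
#' Two intervals window-overlap when they lie on the same chromosome and
#' their extended spans intersect: `a.start < b.end + w` and
#' `b.start < a.end + w`. With `w = 0` this is ordinary half-open overlap.
#' A gap of exactly `w` bases does not count as overlap. This mirrors
#' extending each peak by `w` bp up- and downstream before intersecting.
#'
#' @param a,b Single-row interval tables (or lists with `chrom`, `start`,
#'   `end`).
#' @param w Window size in bp (default 300).
#' @return Logical scalar. Symmetric in `a` and `b`.
#' @examples
#' a <- g_intervals("chr1", 1000, 1200)
#' b <- g_intervals("chr1", 1400, 1500)
#' window_overlaps(a, b, w = 300)  # TRUE: gap 200 < 300
#' @export
window_overlaps <- function(a, b, w = 300) {
  w <- as.integer(w)
  if (is.na(w) || w < 0L) stop("window size w must be a non-negative integer")
  a$chrom == b$chrom && a$start < b$end + w && b$start < a$end + w
}

#' Vectorized windowed overlap of a query set against a subject set
#'
#' @param query,subject Sorted interval tables ([g_intervals()]).
#' @param w Window size in bp.
#' @return Logical vector, one element per query row: `TRUE` iff that query
#'   interval window-overlaps at least one subject interval. Independent of
#'   subject ordering.
#' @export
overlap_any <- function(query, subject, w = 300) {
  if (!is_sorted_intervals(query) || !is_sorted_intervals(subject))
    stop("overlap_any requires sorted interval tables; use sort_intervals()")
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  q <- intervals_to_granges(query)
  s <- intervals_to_granges(subject)
  suppressWarnings(IRanges::overlapsAny(q, s, maxgap = window_maxgap(w)))
}

#' Create a peak collection
#'
#' A peak collection groups the intervals of one sample (typically one
#' replicate of one enrichment library) together with its metadata: which
#' cytosine modification was captured, the experimental condition, the
#' defeat paradigm, and the animal age group.
#'
#' @param intervals Interval table ([g_intervals()]); duplicates by
#'   `(chrom, start, end)` are rejected.
#' @param sample_id Sample identifier.
#' @param mark `"5mC"` or `"5hmC"`.
#' @param condition One of `"control"`, `"susceptible"`, `"resilient"`,
#'   `"stress"`, `"SS"`, `"RR"`.
#' @param paradigm One of `"ASDS"`, `"CSDS"`, `"LSDS"`, or `NA`.
#' @param age `"3mo"`, `"6mo"`, or `NA`.
#' @return An object of class `PeakCollection`.
#' @export
peak_collection <- function(intervals, sample_id, mark = c("5mC", "5hmC"),
                            condition = c("control", "susceptible",
                                          "resilient", "stress", "SS", "RR"),
                            paradigm = NA_character_, age = NA_character_) {
  mark <- match.arg(mark)
  condition <- match.arg(condition)
  if (!is.na(paradigm))
    paradigm <- match.arg(paradigm, c("ASDS", "CSDS", "LSDS"))
  if (!is.na(age)) age <- match.arg(age, c("3mo", "6mo"))
  intervals <- sort_intervals(intervals)
  key <- paste(intervals$chrom, intervals$start, intervals$end)
  if (anyDuplicated(key))
    stop("duplicate (chrom, start, end) intervals within one collection")
  structure(
    list(sample_id = as.character(sample_id), mark = mark,
         condition = condition, paradigm = paradigm, age = age,
         intervals = intervals),
    class = "PeakCollection"
  )
}

#' @export
print.PeakCollection <- function(x, ...) {
  cat(sprintf("PeakCollection '%s': %d peaks [%s, %s, %s, %s]\n",
              x$sample_id, nrow(x$intervals), x$mark, x$condition,
              ifelse(is.na(x$paradigm), "-", x$paradigm),
              ifelse(is.na(x$age), "-", x$age)))
  invisible(x)
}

#' Number of peaks in a collection
#' @param x A `PeakCollection`.
#' @export
length.PeakCollection <- function(x) nrow(x$intervals)

same_peak_metadata <- function(a, b) {
  identical(a$mark, b$mark) && identical(a$condition, b$condition) &&
    identical(a$paradigm, b$paradigm) && identical(a$age, b$age)
}

#' Replicate-consensus peaks under windowed overlap
#'
#' Only peaks supported by every replicate survive. The first replicate in
#' the supplied order is the anchor: its intervals are retained whenever
#' they window-overlap at least one peak in each of the other replicates,
#' and the consensus reports anchor coordinates. With a single replicate
#' the input is returned unchanged.
#'
#' @param replicates List of `PeakCollection`s sharing mark, condition,
#'   paradigm and age. Order matters only through the anchor choice.
#' @param w Window size in bp (default 300).
#' @return A `PeakCollection` whose `sample_id` is
#'   `"consensus(<id1>+<id2>+...)"`; carries attribute `"replicate_ids"`.
#' @export
consensus_peaks <- function(replicates, w = 300) {
  if (length(replicates) == 0) stop("need at least one replicate")
  if (!all(vapply(replicates, inherits, logical(1), "PeakCollection")))
    stop("replicates must be PeakCollection objects")
  anchor <- replicates[[1]]
  for (r in replicates[-1]) {
    if (!same_peak_metadata(anchor, r))
      stop("replicates have mismatched mark/condition/paradigm/age metadata")
  }
  keep <- rep(TRUE, nrow(anchor$intervals))
  for (r in replicates[-1]) {
    keep <- keep & overlap_any(anchor$intervals, r$intervals, w = w)
  }
  ids <- vapply(replicates, function(r) r$sample_id, character(1))
  out <- peak_collection(
    anchor$intervals[keep, , drop = FALSE],
    sample_id = sprintf("consensus(%s)", paste(ids, collapse = "+")),
    mark = anchor$mark, condition = anchor$condition,
    paradigm = anchor$paradigm, age = anchor$age
  )
  attr(out, "replicate_ids") <- ids
  out
}

#' Merge overlapping or nearby intervals
#'
#' @param xs Interval table.
#' @param gap Maximum gap (bp) across which adjacent intervals are joined;
#'   `gap = 0` (default) merges only touching/overlapping intervals and
#'   preserves the union of covered bases.
#' @return Sorted, non-overlapping interval table.
#' @export
merge_intervals <- function(xs, gap = 0) {
  if (nrow(xs) == 0) return(g_intervals(character(0), integer(0), integer(0)))
  gr <- GenomicRanges::reduce(intervals_to_granges(xs),
                              min.gapwidth = as.integer(gap) + 1L)
  granges_to_intervals(gr)
}

#' Total bases covered by an interval set
#'
#' @param xs Interval table (may contain overlapping intervals).
#' @return Integer: number of distinct bases covered.
#' @export
covered_bases <- function(xs) {
  if (nrow(xs) == 0) return(0L)
  sum(GenomicRanges::width(GenomicRanges::reduce(intervals_to_granges(xs))))
}
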