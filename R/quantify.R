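#' Count read midpoints falling in regions
#'
#' Each read is represented by a single fragment-midpoint coordinate and is
#' counted in every region whose half-open span contains it
#' (`start <= p < end`). Midpoint counting is deterministic and unambiguous
#' at region boundaries; any-overlap counting of full fragments is
#' available via `mode = "any"` on fragment intervals.
#'
#' @param regions Sorted interval table.
#' @param reads Either a `data.frame(chrom, pos)` of 0-based midpoint
#'   positions (for `mode = "midpoint"`) or an interval table of fragments
#'   (for `mode = "any"`).
#' @param mode `"midpoint"` (default) or `"any"`.
#' @return Integer vector of counts, one per region row.
#' @export
count_reads_in_regions <- function(regions, reads, mode = c("midpoint", "any")) {
  mode <- match.arg(mode)
  if (!is_sorted_intervals(regions))
    stop("regions must be sorted; use sort_intervals()")
  if (is.null(reads))
    stop("no read data supplied; provide read positions or use a ",
         "precomputed count table")
  rg <- intervals_to_granges(regions)
  if (mode == "midpoint") {
    stopifnot(all(c("chrom", "pos") %in% names(reads)))
    if (nrow(reads) == 0) return(rep(0L, nrow(regions)))
    pts <- GenomicRanges::GRanges(reads$chrom,
                                  IRanges::IRanges(reads$pos + 1L, width = 1L))
    GenomicRanges::countOverlaps(rg, pts)
  } else {
    if (nrow(reads) == 0) return(rep(0L, nrow(regions)))
    GenomicRanges::countOverlaps(rg, intervals_to_granges(reads))
  }
}

#' Build a region quantification matrix
#'
#' Stores raw per-region per-sample counts next to their counts-per-million
#' (CPM) normalization: `norm[i, j] = raw[i, j] / mapped_reads[j] * 1e6`.
#' The CPM scale itself cancels in any fold change; it is kept for
#' interpretability.
#'
#' @param regions Interval table (rows of `raw` follow its order).
#' @param raw Non-negative integer matrix, regions x samples; column names
#'   are sample ids.
#' @param mapped_reads Named numeric vector of total mapped reads per
#'   sample (all `> 0`), names matching `colnames(raw)`.
#' @param conditions Optional named character vector assigning each sample
#'   to a condition group.
#' @return Object of class `RegionQuantMatrix`.
#' @export
region_quant <- function(regions, raw, mapped_reads, conditions = NULL) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw))) stop("raw matrix needs sample ids as colnames")
  if (nrow(raw) != nrow(regions))
    stop("raw matrix rows must match the region table")
  if (!all(colnames(raw) %in% names(mapped_reads)))
    stop("mapped_reads missing for some samples")
  mapped_reads <- mapped_reads[colnames(raw)]
  if (any(!is.finite(mapped_reads)) || any(mapped_reads <= 0))
    stop("mapped_reads must all be positive")
  if (any(raw < 0)) stop("raw counts must be non-negative")
  norm <- sweep(raw, 2, mapped_reads, "/") * 1e6
  structure(
    list(regions = regions, raw = raw, norm = norm,
         mapped_reads = mapped_reads, conditions = conditions),
    class = "RegionQuantMatrix"
  )
}

#' @export
print.RegionQuantMatrix <- function(x, ...) {
  cat(sprintf("RegionQuantMatrix: %d regions x %d samples (CPM-normalized)\n",
              nrow(x$raw), ncol(x$raw)))
  invisible(x)
}

#' Per-region log2 fold change between sample groups
#'
#' Normalized (CPM) counts are averaged within each group by arithmetic
#' mean, then `lfc[i] = log2((mean_stress[i] + p) / (mean_control[i] + p))`.
#' The additive pseudocount `p` (in CPM units) keeps every fold change
#' finite when a group mean is zero.
#'
#' @param quant A `RegionQuantMatrix`.
#' @param stress_samples,control_samples Character vectors of sample ids
#'   (columns of `quant$raw`), at least one each.
#' @param pseudocount Additive pseudocount `p > 0` in CPM (default 0.5).
#' @return `data.frame(id, mean_stress, mean_control, lfc)` with one row
#'   per region, in region order.
#' @export
normalize_and_lfc <- function(quant, stress_samples, control_samples,
                              pseudocount = 0.5) {
  stopifnot(inherits(quant, "RegionQuantMatrix"))
  if (length(stress_samples) < 1 || length(control_samples) < 1)
    stop("need at least one sample per group")
  if (!all(c(stress_samples, control_samples) %in% colnames(quant$norm)))
    stop("unknown sample ids")
  if (!is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  ms <- rowMeans(quant$norm[, stress_samples, drop = FALSE])
  mc <- rowMeans(quant$norm[, control_samples, drop = FALSE])
  data.frame(
    id = quant$regions$id,
    mean_stress = ms, mean_control = mc,
    lfc = log2((ms + pseudocount) / (mc + pseudocount)),
    stringsAsFactors = FALSE
  )
}

#' Region-by-condition log2 fold-change table, grouped and sorted
#'
#' Arranges a set of per-contrast fold-change vectors (all over the same
#' regions) the way enrichment heatmaps are laid out: rows grouped by the
#' sign of a reference contrast's fold change, then ordered by descending
#' absolute reference fold change within each group. Plotting is external;
#' this returns the matrix ready for it.
#'
#' @param lfc_tables Named list of [normalize_and_lfc()] outputs sharing
#'   one region list (same ids, same order).
#' @param reference Name of the contrast used for grouping/sorting
#'   (default: first).
#' @return `data.frame` with `id`, one `lfc` column per contrast, and
#'   `sign_group` (`"+"` for reference lfc `>= 0`, `"-"` otherwise); rows
#'   ordered positive group first, descending `|reference lfc|` within
#'   each group.
#' @export
lfc_matrix <- function(lfc_tables, reference = names(lfc_tables)[1]) {
  stopifnot(length(lfc_tables) >= 1, !is.null(names(lfc_tables)))
  ids <- lfc_tables[[1]]$id
  for (tab in lfc_tables) {
    if (!identical(tab$id, ids))
      stop("all contrasts must be quantified over the identical region list")
  }
  m <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (nm in names(lfc_tables)) m[[nm]] <- lfc_tables[[nm]]$lfc
  ref <- m[[reference]]
  m$sign_group <- ifelse(ref >= 0, "+", "-")
  ord <- order(m$sign_group == "-", -abs(ref))
  m <- m[ord, , drop = FALSE]
  rownames(m) <- NULL
  m
}
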