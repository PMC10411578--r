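#' Construct a differential region set
#'
#' Holds the gained or lost regions for one modification mark and one
#' stress-vs-control contrast, with provenance back to the consensus peak
#' sets they came from.
#'
#' @param regions Interval table (sorted, deduplicated internally).
#' @param mark `"5mC"` or `"5hmC"`.
#' @param direction `"gained"` (region present only in stress) or `"lost"`
#'   (present only in control).
#' @param contrast Named list or character vector describing the contrast
#'   (stress condition, control condition, paradigm, age); free-form.
#' @param provenance Character vector of source consensus identifiers.
#' @return Object of class `DifferentialRegionSet`.
#' @export
differential_region_set <- function(regions, mark = c("5mC", "5hmC"),
                                    direction = c("gained", "lost"),
                                    contrast = NULL, provenance = character(0)) {
  mark <- match.arg(mark)
  direction <- match.arg(direction)
  regions <- sort_intervals(regions)
  key <- paste(regions$chrom, regions$start, regions$end)
  regions <- regions[!duplicated(key), , drop = FALSE]
  structure(
    list(mark = mark, direction = direction, contrast = contrast,
         regions = regions, provenance = provenance),
    class = "DifferentialRegionSet"
  )
}

#' @export
print.DifferentialRegionSet <- function(x, ...) {
  cat(sprintf("DifferentialRegionSet: %d %s %s regions\n",
              nrow(x$regions), x$direction, x$mark))
  invisible(x)
}

#' @export
length.DifferentialRegionSet <- function(x) nrow(x$regions)

#' Call gained and lost differential regions between consensus peak sets
#'
#' Presence/absence calling: a stress consensus peak with no windowed
#' overlap to any control peak is *gained*; a control peak with no windowed
#' overlap to any stress peak is *lost*. No count-based statistical test is
#' applied — differential status is purely peak presence under the window.
#'
#' @param stress,control `PeakCollection`s (replicate consensus) for the
#'   same mark, paradigm and age.
#' @param w Window size in bp (default 300).
#' @return `list(gained = DifferentialRegionSet, lost = DifferentialRegionSet)`.
#' @export
call_differential <- function(stress, control, w = 300) {
  stopifnot(inherits(stress, "PeakCollection"),
            inherits(control, "PeakCollection"))
  if (!identical(stress$mark, control$mark) ||
      !identical(stress$paradigm, control$paradigm) ||
      !identical(stress$age, control$age))
    stop("stress and control collections have mismatched mark/paradigm/age")
  gained_idx <- !overlap_any(stress$intervals, control$intervals, w = w)
  lost_idx <- !overlap_any(control$intervals, stress$intervals, w = w)
  contrast <- list(stress = stress$condition, control = control$condition,
                   paradigm = stress$paradigm, age = stress$age)
  gained <- differential_region_set(
    stress$intervals[gained_idx, , drop = FALSE],
    mark = stress$mark, direction = "gained", contrast = contrast,
    provenance = c(stress$sample_id, control$sample_id))
  lost <- differential_region_set(
    control$intervals[lost_idx, , drop = FALSE],
    mark = stress$mark, direction = "lost", contrast = contrast,
    provenance = c(stress$sample_id, control$sample_id))
  # post-hoc guard: no gained region may touch a control peak under w
  stopifnot(!any(overlap_any(gained$regions, control$intervals, w = w)))
  list(gained = gained, lost = lost)
}

#' Condition-specific differential regions (windowed subtraction)
#'
#' Returns the regions of `primary` with no windowed overlap to any region
#' of `other` — e.g. susceptible-specific gains are the susceptible gained
#' regions minus any that overlap resilient gained regions.
#'
#' @param primary,other `DifferentialRegionSet`s with the same mark and
#'   direction.
#' @param w Window size in bp.
#' @return A `DifferentialRegionSet` of the surviving `primary` regions.
#' @export
condition_specific <- function(primary, other, w = 300) {
  stopifnot(inherits(primary, "DifferentialRegionSet"),
            inherits(other, "DifferentialRegionSet"))
  if (!identical(primary$mark, other$mark))
    stop("mark mismatch between region sets")
  if (!identical(primary$direction, other$direction))
    stop("direction mismatch between region sets")
  keep <- !overlap_any(primary$regions, other$regions, w = w)
  differential_region_set(
    primary$regions[keep, , drop = FALSE],
    mark = primary$mark, direction = primary$direction,
    contrast = primary$contrast,
    provenance = c(primary$provenance, paste0("minus:", other$provenance)))
}

#' Windowed overlap between two differential region sets
#'
#' Lists every region of `a` that window-overlaps at least one region of
#' `b` together with its matched `b` region(s). The shared fraction counts
#' each `a` region once regardless of how many `b` regions it hits, so it
#' is always `<= 1`.
#'
#' @param a,b `DifferentialRegionSet`s with the same mark.
#' @param w Window size in bp.
#' @param check_mark Require `a$mark == b$mark` (default `TRUE`).
#' @return List with `shared` (data.frame of matched `a_id`/`b_id` pairs and
#'   coordinates), `a_only` and `b_only` counts, and `fraction_shared`
#'   (`|shared a| / |a|`; `NA` when `a` is empty).
#' @export
overlap_regions <- function(a, b, w = 300, check_mark = TRUE) {
  stopifnot(inherits(a, "DifferentialRegionSet"),
            inherits(b, "DifferentialRegionSet"))
  if (check_mark && !identical(a$mark, b$mark))
    stop("mark mismatch between region sets")
  na <- nrow(a$regions); nb <- nrow(b$regions)
  if (na == 0 || nb == 0) {
    shared <- data.frame(a_id = character(0), b_id = character(0),
                         stringsAsFactors = FALSE)
    return(list(shared = shared, a_only = na, b_only = nb,
                fraction_shared = if (na == 0) NA_real_ else 0))
  }
  ga <- intervals_to_granges(a$regions)
  gb <- intervals_to_granges(b$regions)
  # disjoint seqlevel sets are a legitimate comparison (zero overlap);
  # silence the informational cross-seqlevel warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(ga, gb, maxgap = window_maxgap(w)))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  shared <- data.frame(
    a_id = a$regions$id[qi],
    a_chrom = a$regions$chrom[qi], a_start = a$regions$start[qi],
    a_end = a$regions$end[qi],
    b_id = b$regions$id[si],
    b_chrom = b$regions$chrom[si], b_start = b$regions$start[si],
    b_end = b$regions$end[si],
    stringsAsFactors = FALSE
  )
  n_shared_a <- length(unique(qi))
  list(shared = shared,
       a_only = na - n_shared_a,
       b_only = nb - length(unique(si)),
       fraction_shared = n_shared_a / na)
}

#' Overlap opposite-direction regions across the two modification marks
#'
#' Intended for gained-5mC vs lost-5hmC (and vice versa), asking whether
#' methylation gains coincide with hydroxymethylation losses at the same
#' loci. Same contract as [overlap_regions()]; same-direction input is
#' allowed but flagged with a warning.
#'
#' @param dmr 5mC `DifferentialRegionSet`.
#' @param dhmr 5hmC `DifferentialRegionSet`.
#' @param w Window size in bp.
#' @return As [overlap_regions()].
#' @export
cross_mark_overlap <- function(dmr, dhmr, w = 300) {
  stopifnot(inherits(dmr, "DifferentialRegionSet"),
            inherits(dhmr, "DifferentialRegionSet"))
  if (!identical(dmr$mark, "5mC") || !identical(dhmr$mark, "5hmC"))
    stop("cross_mark_overlap expects a 5mC set and a 5hmC set, in that order")
  if (identical(dmr$direction, dhmr$direction))
    warning("cross-mark overlap of same-direction sets; ",
            "the intended use is gained vs lost")
  overlap_regions(dmr, dhmr, w = w, check_mark = FALSE)
}
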