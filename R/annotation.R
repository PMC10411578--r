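#' Construct a gene model
#'
#' A minimal gene model for nearest-gene annotation and genomic-feature
#' classification: per-gene span, strand and exon structure over a genome
#' of known chromosome lengths. Coordinates are 0-based half-open. The TSS
#' is `tx_start` on the `+` strand and `tx_end - 1` on the `-` strand.
#'
#' @param genes `data.frame(gene_id, symbol, chrom, strand, tx_start,
#'   tx_end)`; strand must be `"+"` or `"-"`.
#' @param exons `data.frame(gene_id, chrom, start, end)`; every exon must
#'   lie within its gene's span.
#' @param genome `data.frame(chrom, length)` of chromosome sizes.
#' @return Object of class `GeneModel`.
#' @export
gene_model <- function(genes, exons, genome) {
  stopifnot(all(c("gene_id", "symbol", "chrom", "strand",
                  "tx_start", "tx_end") %in% names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)),
            all(c("chrom", "length") %in% names(genome)))
  if (nrow(genes) > 0) {
    if (!all(genes$strand %in% c("+", "-")))
      stop("gene strand must be '+' or '-'")
    if (any(genes$tx_end <= genes$tx_start))
      stop("gene tx_end must exceed tx_start")
    span <- genes[match(exons$gene_id, genes$gene_id), ]
    if (any(exons$start < span$tx_start) || any(exons$end > span$tx_end))
      stop("exons must lie within their gene span")
  }
  genes <- genes[order(genes$chrom, genes$tx_start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons, genome = genome),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel: %d genes, %d exons, %d chromosomes (%d bp)\n",
              nrow(x$genes), nrow(x$exons), nrow(x$genome),
              sum(x$genome$length)))
  invisible(x)
}

# 0-based TSS / TES base position per gene, strand-aware.
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
}
gene_tes <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_end - 1L, genes$tx_start)
}

# Oriented window around an anchor base -> half-open genomic interval,
# clipped to the chromosome. `win` is c(upstream_offset, downstream_offset)
# in gene orientation, inclusive at both ends (e.g. promoter c(-1000, 100)).
oriented_window <- function(anchor, strand, win, chrom_len) {
  lo <- ifelse(strand == "+", anchor + win[1], anchor - win[2])
  hi <- ifelse(strand == "+", anchor + win[2], anchor - win[1])
  lo <- pmax(lo, 0L)
  hi <- pmin(hi, chrom_len - 1L)
  data.frame(start = as.integer(lo), end = as.integer(hi + 1L))
}

# Disjoint priority partition of the genome into promoter > TTS > exon >
# intron > intergenic, as GRanges per class.
feature_partition <- function(model, promoter_window = c(-1000, 100),
                              tts_window = c(-100, 1000)) {
  genome_gr <- GenomicRanges::GRanges(
    model$genome$chrom,
    IRanges::IRanges(1L, model$genome$length))
  g <- model$genes
  if (nrow(g) == 0) {
    empty <- GenomicRanges::GRanges()
    return(list(promoter = empty, TTS = empty, exon = empty, intron = empty,
                intergenic = genome_gr))
  }
  clen <- model$genome$length[match(g$chrom, model$genome$chrom)]
  pw <- oriented_window(gene_tss(g), g$strand, promoter_window, clen)
  tw <- oriented_window(gene_tes(g), g$strand, tts_window, clen)
  to_gr <- function(chrom, df) GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(df$start + 1L, df$end)))
  prom <- to_gr(g$chrom, pw)
  tts <- GenomicRanges::setdiff(to_gr(g$chrom, tw), prom)
  exon_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    model$exons$chrom,
    IRanges::IRanges(model$exons$start + 1L, model$exons$end)))
  covered <- GenomicRanges::union(prom, tts)
  exon <- GenomicRanges::setdiff(exon_gr, covered)
  covered <- GenomicRanges::union(covered, exon)
  span_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$tx_start + 1L, g$tx_end)))
  intron <- GenomicRanges::setdiff(span_gr, covered)
  covered <- GenomicRanges::union(covered, intron)
  intergenic <- GenomicRanges::setdiff(genome_gr, covered)
  list(promoter = prom, TTS = tts, exon = exon, intron = intron,
       intergenic = intergenic)
}

region_midpoints <- function(regions) {
  (regions$start + regions$end) %/% 2L
}

#' Classify regions into genomic feature classes
#'
#' Each region is represented by its midpoint base, which is assigned the
#' highest-priority feature it falls in: promoter > TTS > exon > intron >
#' intergenic. Promoter and TTS windows are oriented by gene strand and
#' inclusive at both offsets.
#'
#' @param regions Interval table.
#' @param model A `GeneModel`.
#' @param promoter_window Offsets around the TSS, default `c(-1000, 100)` bp.
#' @param tts_window Offsets around the transcription end, default
#'   `c(-100, 1000)` bp.
#' @return Character vector of feature classes, one per region.
#' @export
classify_feature <- function(regions, model, promoter_window = c(-1000, 100),
                             tts_window = c(-100, 1000)) {
  part <- feature_partition(model, promoter_window, tts_window)
  mids <- region_midpoints(regions)
  pts <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(mids + 1L, width = 1L))
  out <- rep("intergenic", nrow(regions))
  for (feat in c("intron", "exon", "TTS", "promoter")) {
    hit <- IRanges::overlapsAny(pts, part[[feat]])
    out[hit] <- feat
  }
  out
}

#' Nearest gene by TSS distance
#'
#' For each region midpoint, returns the gene minimizing the absolute
#' distance to its TSS; ties are broken by smaller `tx_start`, then by
#' lexicographic `gene_id`, making the assignment independent of gene
#' order in the model. The distance is signed in gene orientation
#' (negative = upstream of the TSS). Regions on chromosomes absent from
#' the model get empty gene fields and `NA` distance.
#'
#' @param regions Interval table.
#' @param model A `GeneModel`.
#' @return `data.frame(id, gene_id, symbol, tss_distance)` in region order.
#' @export
nearest_gene <- function(regions, model) {
  if (nrow(model$genes) == 0) stop("gene model is empty")
  g <- model$genes
  tss <- gene_tss(g)
  mids <- region_midpoints(regions)
  n <- nrow(regions)
  gene_id <- rep(NA_character_, n)
  symbol <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    on_chr <- which(g$chrom == regions$chrom[i])
    if (length(on_chr) == 0) next
    d <- abs(mids[i] - tss[on_chr])
    best <- on_chr[order(d, g$tx_start[on_chr], g$gene_id[on_chr])][1]
    gene_id[i] <- g$gene_id[best]
    symbol[i] <- g$symbol[best]
    dist[i] <- if (g$strand[best] == "+") mids[i] - tss[best]
               else tss[best] - mids[i]
  }
  data.frame(id = regions$id, gene_id = gene_id, symbol = symbol,
             tss_distance = dist, stringsAsFactors = FALSE)
}

#' Annotate regions with nearest gene and feature class
#'
#' Gene assignment (nearest TSS) and feature class (midpoint priority
#' partition) are resolved independently, so a region may classify as
#' `exon` through one gene while being nearest another gene's TSS; both
#' are recorded.
#'
#' @inheritParams classify_feature
#' @return `data.frame(id, chrom, start, end, gene_id, symbol,
#'   tss_distance, feature)`, one row per region, region order preserved.
#' @export
annotate_regions <- function(regions, model, promoter_window = c(-1000, 100),
                             tts_window = c(-100, 1000)) {
  ng <- nearest_gene(regions, model)
  feat <- classify_feature(regions, model, promoter_window, tts_window)
  out <- data.frame(id = regions$id, chrom = regions$chrom,
                    start = regions$start, end = regions$end,
                    gene_id = ng$gene_id, symbol = ng$symbol,
                    tss_distance = ng$tss_distance, feature = feat,
                    stringsAsFactors = FALSE)
  # a midpoint outside every gene-derived feature carries no gene call
  out$gene_id[out$feature == "intergenic" & is.na(out$gene_id)] <- NA_character_
  out
}

#' Observed vs expected genomic-feature distribution of a region set
#'
#' Observed fractions come from midpoint feature classification; expected
#' fractions are each feature's share of genome bases under the identical
#' priority partition. Classes with zero observed regions report `NA`
#' log2 ratios rather than `-Inf`.
#'
#' @inheritParams classify_feature
#' @return `data.frame(feature, n, observed, expected, log2_ratio)` over
#'   the five feature classes.
#' @export
feature_enrichment <- function(regions, model,
                               promoter_window = c(-1000, 100),
                               tts_window = c(-100, 1000)) {
  if (nrow(regions) == 0) stop("feature_enrichment needs at least one region")
  feats <- c("promoter", "TTS", "exon", "intron", "intergenic")
  obs_class <- classify_feature(regions, model, promoter_window, tts_window)
  part <- feature_partition(model, promoter_window, tts_window)
  widths <- vapply(part, function(gr) sum(as.numeric(GenomicRanges::width(gr))),
                   numeric(1))
  expected <- widths[feats] / sum(model$genome$length)
  n <- vapply(feats, function(f) sum(obs_class == f), numeric(1))
  observed <- n / nrow(regions)
  lr <- ifelse(n == 0, NA_real_, log2(observed / expected))
  data.frame(feature = feats, n = as.integer(n), observed = observed,
             expected = as.numeric(expected), log2_ratio = lr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove intergenic regions from an annotated table
#'
#' Regions whose midpoint falls outside every gene-derived feature carry no
#' interpretable gene link and are dropped before expression correlation.
#'
#' @param annotated Output of [annotate_regions()].
#' @return The rows with `feature != "intergenic"`, order preserved.
#' @export
drop_intergenic <- function(annotated) {
  out <- annotated[annotated$feature != "intergenic", , drop = FALSE]
  rownames(out) <- NULL
  out
}
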