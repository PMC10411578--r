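#' Read peak intervals from a BED or narrowPeak file
#'
#' BED3/BED6 and MACS2 narrowPeak are supported; coordinates are kept
#' 0-based half-open. Extra narrowPeak columns are preserved as attribute
#' `"payload"` on the returned table.
#'
#' @param path Path to a BED/narrowPeak file.
#' @param format `"bed"` (default) or `"narrowPeak"`.
#' @return Sorted interval table; the BED name column (when present)
#'   populates `id`.
#' @export
read_peaks_bed <- function(path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "narrowPeak") {
    gr <- rtracklayer::import(path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
  } else {
    gr <- rtracklayer::import(path, format = "BED")
  }
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NULL
  out <- granges_to_intervals(gr, id = nm)
  if (format == "narrowPeak") {
    attr(out, "payload") <- S4Vectors::mcols(gr)[
      , c("signalValue", "pValue", "qValue", "peak"), drop = FALSE]
  }
  out
}

#' Write intervals as BED6
#'
#' The region id goes in the name column; score 0, strand ".".
#'
#' @param xs Interval table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(xs, path) {
  if (nrow(xs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(xs$chrom, xs$start, xs$end, xs$id, 0L, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene model from a GTF file
#'
#' Uses `gene` and `exon` features. Gene id/symbol are taken from the
#' `gene_id` and `gene_name` attributes (symbol falls back to gene id).
#'
#' @param path GTF path.
#' @param genome Optional `data.frame(chrom, length)` of chromosome sizes
#'   (see [read_chrom_sizes()]); if omitted, each chromosome's length is
#'   inferred as the maximum annotated end coordinate.
#' @return A `GeneModel` (see [gene_model()]).
#' @export
read_gene_model <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  g <- gr[gr$type == "gene"]
  e <- gr[gr$type == "exon"]
  sym <- if (!is.null(g$gene_name)) as.character(g$gene_name)
         else as.character(g$gene_id)
  sym[is.na(sym)] <- as.character(g$gene_id)[is.na(sym)]
  genes <- data.frame(
    gene_id = as.character(g$gene_id),
    symbol = sym,
    chrom = as.character(GenomeInfoDb::seqnames(g)),
    strand = as.character(GenomicRanges::strand(g)),
    tx_start = GenomicRanges::start(g) - 1L,
    tx_end = GenomicRanges::end(g),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = as.character(e$gene_id),
    chrom = as.character(GenomeInfoDb::seqnames(e)),
    start = GenomicRanges::start(e) - 1L,
    end = GenomicRanges::end(e),
    stringsAsFactors = FALSE
  )
  if (is.null(genome)) {
    mx <- tapply(genes$tx_end, genes$chrom, max)
    genome <- data.frame(chrom = names(mx), length = as.integer(mx),
                         stringsAsFactors = FALSE)
  }
  gene_model(genes, exons, genome)
}

#' Write a gene model as GTF
#'
#' Emits `gene` and `exon` features with `gene_id`/`gene_name` attributes;
#' deterministic output (stable ordering, no timestamps).
#'
#' @param model A `GeneModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gtf <- function(model, path) {
  g <- model$genes
  e <- model$exons
  attr_of <- function(id, sym) sprintf('gene_id "%s"; gene_name "%s";', id, sym)
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, paste(g$chrom[i], "stressDMR", "gene",
                            g$tx_start[i] + 1L, g$tx_end[i], ".",
                            g$strand[i], ".",
                            attr_of(g$gene_id[i], g$symbol[i]), sep = "\t"))
    ex <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(ex$chrom[j], "stressDMR", "exon",
                              ex$start[j] + 1L, ex$end[j], ".",
                              g$strand[i], ".",
                              attr_of(g$gene_id[i], g$symbol[i]), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path File path.
#' @return `data.frame(chrom, length)`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  df$length <- as.integer(df$length)
  df
}

#' Read an expression table
#'
#' Tab-separated with columns `gene_id`, `symbol`, `log2fc` and optionally
#' `q_value` (Cuffdiff-style differential expression output).
#'
#' @param path TSV path.
#' @return `data.frame(gene_id, symbol, expr_lfc, q_value)`.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "symbol", "log2fc") %in% names(df)))
  out <- data.frame(gene_id = as.character(df$gene_id),
                    symbol = as.character(df$symbol),
                    expr_lfc = as.numeric(df$log2fc),
                    q_value = if ("q_value" %in% names(df))
                      as.numeric(df$q_value) else NA_real_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id rows in expression table: ", path)
  if (any(!is.finite(out$expr_lfc)))
    stop("non-finite log2fc in expression table: ", path)
  out
}

# Deterministic TSV writer shared by all pipeline outputs.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
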