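# Independent brute-force oracles. All work directly on 0-based half-open
# coordinates by explicit enumeration or all-pairs loops -- no IRanges.

# windowed overlap by explicit +/- w extension of the first interval
oracle_pair_overlap <- function(c1, s1, e1, c2, s2, e2, w) {
  if (c1 != c2) return(FALSE)
  (s1 - w) < e2 && s2 < (e1 + w)
}

# all-pairs loop: for each query row, any subject row it window-overlaps
oracle_overlap_any <- function(query, subject, w) {
  vapply(seq_len(nrow(query)), function(i) {
    any(vapply(seq_len(nrow(subject)), function(j) {
      oracle_pair_overlap(query$chrom[i], query$start[i], query$end[i],
                          subject$chrom[j], subject$start[j],
                          subject$end[j], w)
    }, logical(1)))
  }, logical(1))
}

# covered bases via a per-base boolean mask (single chromosome)
oracle_covered_bases <- function(xs, chrom_len) {
  mask <- logical(chrom_len)
  for (i in seq_len(nrow(xs))) {
    mask[(xs$start[i] + 1):xs$end[i]] <- TRUE
  }
  sum(mask)
}

# exhaustive nearest-gene scan with the tie-break rule
oracle_nearest_gene <- function(chrom, midpoint, genes) {
  on_chr <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(on_chr) == 0) return(NA_character_)
  tss <- ifelse(on_chr$strand == "+", on_chr$tx_start, on_chr$tx_end - 1L)
  d <- abs(midpoint - tss)
  on_chr$gene_id[order(d, on_chr$tx_start, on_chr$gene_id)][1]
}

# per-position feature classification by looping over genes and applying
# the promoter > TTS > exon > intron priority directly
oracle_feature_at <- function(chrom, pos, model,
                              pw = c(-1000, 100), tw = c(-100, 1000)) {
  g <- model$genes[model$genes$chrom == chrom, , drop = FALSE]
  in_prom <- FALSE; in_tts <- FALSE; in_exon <- FALSE; in_gene <- FALSE
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "+") {
      tss <- g$tx_start[i]; tes <- g$tx_end[i] - 1L
      off_tss <- pos - tss; off_tes <- pos - tes
    } else {
      tss <- g$tx_end[i] - 1L; tes <- g$tx_start[i]
      off_tss <- tss - pos; off_tes <- tes - pos
    }
    if (off_tss >= pw[1] && off_tss <= pw[2]) in_prom <- TRUE
    if (off_tes >= tw[1] && off_tes <= tw[2]) in_tts <- TRUE
    if (pos >= g$tx_start[i] && pos < g$tx_end[i]) in_gene <- TRUE
    ex <- model$exons[model$exons$gene_id == g$gene_id[i], , drop = FALSE]
    if (any(pos >= ex$start & pos < ex$end)) in_exon <- TRUE
  }
  if (in_prom) "promoter"
  else if (in_tts) "TTS"
  else if (in_exon) "exon"
  else if (in_gene) "intron"
  else "intergenic"
}

# random sorted interval set on a toy genome (deduplicated coordinates)
random_intervals <- function(n, chroms = c("chrA", "chrB"),
                             genome_len = 1e5, max_width = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(genome_len - max_width - 1L, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  df <- data.frame(chrom = chrom, start = start, end = start + width,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[, c("chrom", "start", "end")]), , drop = FALSE]
  g_intervals(df$chrom, df$start, df$end)
}

# small gene model used across annotation tests
toy_gene_model <- function(n_genes = 20, chrom_len = 100000L, seed = 42) {
  set.seed(seed)
  bin <- chrom_len %/% n_genes
  s <- (seq_len(n_genes) - 1L) * bin + sample.int(bin %/% 4, n_genes)
  glen <- bin %/% 2
  genes <- data.frame(
    gene_id = sprintf("T%03d", seq_len(n_genes)),
    symbol = sprintf("Toy%03d", seq_len(n_genes)),
    chrom = "chrA", strand = sample(c("+", "-"), n_genes, replace = TRUE),
    tx_start = s, tx_end = s + glen, stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    seg <- glen %/% 3
    data.frame(gene_id = genes$gene_id[i], chrom = "chrA",
               start = s[i] + (0:2) * seg,
               end = s[i] + (0:2) * seg + seg %/% 2,
               stringsAsFactors = FALSE)
  }))
  gene_model(genes, exons,
             data.frame(chrom = "chrA", length = chrom_len,
                        stringsAsFactors = FALSE))
}

make_collection <- function(intervals, id = "s1", condition = "control",
                            mark = "5mC") {
  peak_collection(intervals, sample_id = id, mark = mark,
                  condition = condition, paradigm = "CSDS", age = "3mo")
}
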