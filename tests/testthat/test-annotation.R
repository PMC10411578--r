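test_that("nearest gene minimizes TSS distance with deterministic ties", {
  genes <- data.frame(
    gene_id = c("gA", "gB"), symbol = c("A", "B"), chrom = "chrA",
    strand = "+", tx_start = c(9000L, 12000L), tx_end = c(11000L, 14000L),
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gA", "gB"), chrom = "chrA",
                      start = c(9000L, 12000L), end = c(9500L, 12500L),
                      stringsAsFactors = FALSE)
  model <- gene_model(genes, exons,
                      data.frame(chrom = "chrA", length = 50000L))
  r <- g_intervals("chrA", 9900, 10100)  # midpoint 10000
  ng <- nearest_gene(r, model)
  expect_equal(ng$gene_id, "gA")
  expect_equal(ng$tss_distance, 1000)

  # midpoint exactly on a TSS
  r0 <- g_intervals("chrA", 11950, 12050)
  expect_equal(nearest_gene(r0, model)$tss_distance, 0)

  # minus-strand signing: upstream of the TSS is negative
  genes$strand <- "-"
  model_m <- gene_model(genes, exons,
                        data.frame(chrom = "chrA", length = 50000L))
  rup <- g_intervals("chrA", 11100, 11300)  # midpoint 11200, gA TSS 10999
  ngm <- nearest_gene(rup, model_m)
  expect_equal(ngm$gene_id, "gA")
  expect_equal(ngm$tss_distance, 10999 - 11200)

  # chromosome absent from the model
  off <- nearest_gene(g_intervals("chrZ", 0, 100), model)
  expect_true(is.na(off$gene_id))
})

test_that("nearest gene matches the exhaustive scan and ignores gene order", {
  model <- toy_gene_model(20)
  set.seed(131)
  regions <- random_intervals(100, chroms = "chrA", genome_len = 99000)
  got <- nearest_gene(regions, model)
  oracle <- vapply(seq_len(nrow(regions)), function(i)
    oracle_nearest_gene(regions$chrom[i],
                        (regions$start[i] + regions$end[i]) %/% 2L,
                        model$genes), character(1))
  expect_identical(got$gene_id, oracle)
  # permuting model gene order changes nothing
  perm <- model
  perm$genes <- perm$genes[sample(nrow(perm$genes)), ]
  expect_identical(nearest_gene(regions, perm)$gene_id, got$gene_id)
})

test_that("feature classification matches the per-position oracle", {
  model <- toy_gene_model(8, chrom_len = 40000L)
  set.seed(141)
  pos <- sort(sample.int(39999L, 300)) - 1L
  regions <- g_intervals("chrA", pos, pos + 1L)
  got <- classify_feature(regions, model)
  oracle <- vapply(pos, function(p) oracle_feature_at("chrA", p, model),
                   character(1))
  expect_identical(got, oracle)
})

test_that("priority windows classify promoter and exon correctly", {
  genes <- data.frame(gene_id = "g1", symbol = "G1", chrom = "chrA",
                      strand = "+", tx_start = 10000L, tx_end = 20000L,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", chrom = "chrA",
                      start = c(10000L, 15000L), end = c(10500L, 15800L),
                      stringsAsFactors = FALSE)
  model <- gene_model(genes, exons,
                      data.frame(chrom = "chrA", length = 50000L))
  # midpoint 500 bp upstream of the + strand TSS: promoter
  expect_equal(classify_feature(g_intervals("chrA", 9450, 9550), model),
               "promoter")
  # inside exon 2, outside promoter/TTS windows
  expect_equal(classify_feature(g_intervals("chrA", 15350, 15450), model),
               "exon")
  # inside the gene body between exons
  expect_equal(classify_feature(g_intervals("chrA", 13000, 13100), model),
               "intron")
  # just inside the termination window
  expect_equal(classify_feature(g_intervals("chrA", 20350, 20450), model),
               "TTS")
  expect_equal(classify_feature(g_intervals("chrA", 40000, 40100), model),
               "intergenic")
})

test_that("the feature partition tiles the genome exactly once", {
  model <- toy_gene_model(10, chrom_len = 30000L)
  fe <- feature_enrichment(g_intervals("chrA", 0, 100), model)
  expect_equal(sum(fe$expected), 1.0, tolerance = 1e-12)
  # classifying every 10th base reproduces expected fractions within 1/k
  pos <- seq(0L, 29999L, by = 10L)
  cls <- classify_feature(g_intervals("chrA", pos, pos + 1L), model)
  obs <- table(factor(cls, levels = fe$feature)) / length(pos)
  expect_equal(as.numeric(obs), fe$expected, tolerance = 0.01)
})

test_that("feature enrichment recovers planted exon placement", {
  model <- toy_gene_model(10, chrom_len = 50000L)
  part_exons <- model$exons
  set.seed(151)
  # plant 70% of regions inside exons, 30% uniform
  n_ex <- 350
  ei <- sample(nrow(part_exons), n_ex, replace = TRUE)
  epos <- part_exons$start[ei] +
    sapply(part_exons$end[ei] - part_exons$start[ei], function(wd)
      sample.int(wd, 1) - 1L)
  upos <- sample.int(49998L, 150) - 1L
  regions <- g_intervals("chrA", c(epos, upos), c(epos, upos) + 1L)
  fe <- feature_enrichment(regions, model)
  ex_row <- fe[fe$feature == "exon", ]
  # most planted exonic midpoints classify as exon (a few fall in
  # promoter/TTS windows, which take priority)
  expect_gte(ex_row$observed, 0.5)
  expect_gte(ex_row$log2_ratio, 1.5)
  expect_error(feature_enrichment(regions[0, ], model), "at least one")
})

test_that("drop_intergenic removes exactly the flagged rows, idempotently", {
  ann <- data.frame(id = sprintf("r%03d", 1:100),
                    feature = "intron", stringsAsFactors = FALSE)
  set.seed(161)
  planted <- sample(100, 37)
  ann$feature[planted] <- "intergenic"
  out <- drop_intergenic(ann)
  expect_equal(nrow(out), 63)
  expect_false(any(out$id %in% ann$id[planted]))
  expect_identical(drop_intergenic(out), out)
  expect_equal(nrow(drop_intergenic(ann[planted, ])), 0)
  all_genic <- ann[-planted, ]
  expect_equal(drop_intergenic(all_genic)$id, all_genic$id)
})

test_that("GTF round trip preserves the gene model", {
  model <- toy_gene_model(5, chrom_len = 20000L)
  path <- tempfile(fileext = ".gtf")
  write_gene_model_gtf(model, path)
  back <- read_gene_model(path, genome = model$genome)
  expect_equal(back$genes[, c("gene_id", "chrom", "strand", "tx_start",
                              "tx_end")],
               model$genes[, c("gene_id", "chrom", "strand", "tx_start",
                               "tx_end")])
  expect_equal(nrow(back$exons), nrow(model$exons))
  expect_equal(sort(back$exons$start), sort(model$exons$start))
})
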