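#' Default run configuration for a synthetic-data directory
#'
#' Builds the configuration [run_full_analysis()] consumes, pointing at
#' the files [simulate_all()] writes. Every analysis parameter carries its
#' default (overlap window 300 bp, CPM pseudocount 0.5, trajectory dead
#' zone 0.1, candidate expression threshold 0.25, promoter window
#' -1000/+100, termination window -100/+1000).
#'
#' @param input_dir Directory holding the input files.
#' @param n_replicates Replicate peak files per condition.
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function(input_dir, n_replicates = 3) {
  cfg <- list(
    input_dir = input_dir,
    window = 300, pseudocount = 0.5, epsilon = 0.1,
    candidate_threshold = 0.25,
    promoter_window = c(-1000, 100), tts_window = c(-100, 1000),
    mark = "5mC", paradigm = "CSDS", age = "3mo",
    inputs = list(
      genome = "genome.chrom.sizes", gtf = "genes.gtf",
      peaks = lapply(
        stats::setNames(nm = c("susceptible", "resilient", "control")),
        function(cond) sprintf("peaks_%s_rep%d.bed", cond,
                               seq_len(n_replicates))),
      counts = "region_counts.tsv",
      library_manifest = "library_manifest.tsv",
      expression_3mo = "expression_3mo.tsv",
      expression_6mo = "expression_6mo.tsv",
      temporal = "temporal_profiles.tsv",
      behavior = "behavior.csv"
    )
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a run configuration from YAML
#'
#' Unstated fields fall back to the defaults of [default_run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- default_run_config(y$input_dir %||% dirname(path))
  for (nm in names(y)) base[[nm]] <- y[[nm]]
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_count_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(df)))
  regions <- g_intervals(df$chrom, df$start, df$end, id = df$region_id)
  raw <- as.matrix(df[, setdiff(names(df),
                                c("region_id", "chrom", "start", "end")),
                      drop = FALSE])
  raw <- raw[match(regions$id, df$region_id), , drop = FALSE]
  rownames(raw) <- regions$id
  list(regions = regions, raw = raw)
}

diff_to_annotated_genes <- function(dset, model, cfg) {
  ann <- annotate_regions(dset$regions, model,
                          promoter_window = cfg$promoter_window,
                          tts_window = cfg$tts_window)
  ann$direction <- rep(dset$direction, nrow(ann))
  ann$mark <- rep(dset$mark, nrow(ann))
  ann
}

#' Run the full analysis chain on one configured data set
#'
#' Executes consensus peak calling per condition, presence/absence
#' differential calling for susceptible and resilient vs control,
#' condition-specific subtraction, CPM quantification with per-region
#' log2 fold changes, nearest-gene/feature annotation with intergenic
#' filtering, concomitant gene classification against expression,
#' cross-age candidate filtering, temporal trajectory classification, and
#' behavioral scoring. All stage outputs are written with stable
#' filenames; a machine-readable JSON manifest records parameters, input
#' checksums and per-stage record counts. Reruns on identical inputs and
#' configuration are byte-identical (the pipeline itself draws no random
#' numbers).
#'
#' @param cfg A `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param outdir Output directory, created if needed.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_full_analysis <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ip <- function(nm) file.path(cfg$input_dir, nm)
  op <- function(nm) file.path(outdir, nm)
  counts_rec <- list()
  note <- function(stage, n) {
    message(sprintf("[%s] %d records", stage, n))
    counts_rec[[stage]] <<- n
  }

  genome <- read_chrom_sizes(ip(cfg$inputs$genome))
  model <- read_gene_model(ip(cfg$inputs$gtf), genome = genome)

  # replicate consensus per condition
  consensus <- list()
  for (cond in names(cfg$inputs$peaks)) {
    reps <- lapply(seq_along(cfg$inputs$peaks[[cond]]), function(r) {
      peak_collection(read_peaks_bed(ip(cfg$inputs$peaks[[cond]][r])),
                      sample_id = sprintf("%s_rep%d", cond, r),
                      mark = cfg$mark, condition = cond,
                      paradigm = cfg$paradigm, age = cfg$age)
    })
    note(sprintf("peaks_in_%s", cond),
         sum(vapply(reps, length, integer(1))))
    consensus[[cond]] <- consensus_peaks(reps, w = cfg$window)
    note(sprintf("consensus_%s", cond), length(consensus[[cond]]))
    write_bed(consensus[[cond]]$intervals,
              op(sprintf("consensus_%s.bed", cond)))
  }

  # differential calling and condition-specific subtraction
  diff <- list(
    susceptible = call_differential(consensus$susceptible,
                                    consensus$control, w = cfg$window),
    resilient = call_differential(consensus$resilient, consensus$control,
                                  w = cfg$window))
  specific <- list(
    susceptible = list(
      gained = condition_specific(diff$susceptible$gained,
                                  diff$resilient$gained, w = cfg$window),
      lost = condition_specific(diff$susceptible$lost,
                                diff$resilient$lost, w = cfg$window)),
    resilient = list(
      gained = condition_specific(diff$resilient$gained,
                                  diff$susceptible$gained, w = cfg$window),
      lost = condition_specific(diff$resilient$lost,
                                diff$susceptible$lost, w = cfg$window)))
  diff_manifest <- NULL
  for (cond in names(diff)) {
    for (dir_ in c("gained", "lost")) {
      dset <- diff[[cond]][[dir_]]
      note(sprintf("%s_%s", dir_, cond), length(dset))
      write_bed(dset$regions, op(sprintf("dmr_%s_%s.bed", cond, dir_)))
      sset <- specific[[cond]][[dir_]]
      write_bed(sset$regions,
                op(sprintf("dmr_%s_%s_specific.bed", cond, dir_)))
      diff_manifest <- rbind(diff_manifest, data.frame(
        mark = dset$mark, condition = cond, direction = dir_,
        n_regions = length(dset), n_specific = length(sset),
        window = cfg$window, stringsAsFactors = FALSE))
    }
  }
  write_tsv(diff_manifest, op("differential_manifest.tsv"))

  # quantification: CPM + log2 fold change over the count-table regions
  ct <- read_count_table(ip(cfg$inputs$counts))
  manifest_lib <- utils::read.table(ip(cfg$inputs$library_manifest),
                                    sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
  quant <- region_quant(ct$regions, ct$raw,
                        stats::setNames(manifest_lib$mapped_reads,
                                        manifest_lib$sample_id))
  lfc <- normalize_and_lfc(
    quant,
    manifest_lib$sample_id[manifest_lib$condition != "control"],
    manifest_lib$sample_id[manifest_lib$condition == "control"],
    pseudocount = cfg$pseudocount)
  note("quantified_regions", nrow(lfc))
  write_tsv(lfc, op("region_lfc.tsv"))

  # annotation of differential regions; intergenic regions removed
  ann <- rbind(diff_to_annotated_genes(diff$susceptible$gained, model, cfg),
               diff_to_annotated_genes(diff$susceptible$lost, model, cfg))
  note("annotated", nrow(ann))
  genic <- drop_intergenic(ann)
  note("genic", nrow(genic))
  write_tsv(ann, op("annotated_regions.tsv"))

  # concomitance against expression, cross-age candidates
  expr3 <- read_expression_table(ip(cfg$inputs$expression_3mo))
  expr6 <- read_expression_table(ip(cfg$inputs$expression_6mo))
  conc <- classify_concomitant(genic, expr3)
  note("concomitant_classified", nrow(conc$classified))
  write_tsv(conc$classified, op("concomitant_genes.tsv"))
  dd <- dedup_genes(
    conc$classified$gene_id[conc$classified$direction == "gained"],
    conc$classified$gene_id[conc$classified$direction == "lost"])
  cand_in <- unique(conc$classified[
    conc$classified$gene_id %in% c(dd$gain, dd$loss),
    c("gene_id", "symbol", "direction")])
  cand <- top_candidates(cand_in, expr3, expr6,
                         threshold = cfg$candidate_threshold)
  note("top_candidates", nrow(cand$retained))
  write_tsv(cand$retained, op("top_candidates.tsv"))

  # temporal trajectories
  tp <- utils::read.table(ip(cfg$inputs$temporal), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  prof <- temporal_profiles(tp$id, tp$lfc_A, tp$lfc_C, tp$lfc_L,
                            tp$expr_A, tp$expr_C, tp$expr_L,
                            epsilon = cfg$epsilon)
  note("temporal_profiles", nrow(prof))
  write_tsv(prof, op("temporal_groups.tsv"))

  # behavior
  beh <- utils::read.csv(ip(cfg$inputs$behavior), stringsAsFactors = FALSE)
  scored <- score_behavior(beh)
  note("behavior_scored", nrow(scored))
  utils::write.csv(scored, op("behavior_scored.csv"), row.names = FALSE,
                   quote = FALSE)

  input_files <- c(cfg$inputs$genome, cfg$inputs$gtf,
                   unlist(cfg$inputs$peaks), cfg$inputs$counts,
                   cfg$inputs$library_manifest, cfg$inputs$expression_3mo,
                   cfg$inputs$expression_6mo, cfg$inputs$temporal,
                   cfg$inputs$behavior)
  run_manifest <- list(
    parameters = cfg[c("window", "pseudocount", "epsilon",
                       "candidate_threshold", "promoter_window",
                       "tts_window", "mark", "paradigm", "age")],
    statistical_testing = paste(
      "none: differential regions are presence/absence calls under the",
      "overlap window, not count-based statistical tests"),
    input_checksums = {
      ck <- tools::md5sum(vapply(input_files, ip, character(1)))
      names(ck) <- input_files
      as.list(ck)
    },
    record_counts = counts_rec
  )
  jsonlite::write_json(run_manifest, op("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run_manifest)
}
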