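#' Simulation configuration with planted ground truth parameters
#'
#' Defines the study conditions the generator emulates: replicate
#' enrichment peak sets over a toy genome with planted gained/lost
#' regions, negative-binomial region counts scaled by library size,
#' expression fold changes correlated with the planted modification
#' changes at the study's concomitance rates (40% upregulation given a
#' gain, 58% downregulation given a loss), temporal trajectory groups, and
#' a behavioral cohort with ~20% resilient animals.
#'
#' @param seed Master seed; per-component child seeds are derived as
#'   `(seed + 97 * stage) mod 2147483629` with a fixed stage index per
#'   component (genome 1, peaks 2, counts 3, expression 4, temporal 5,
#'   behavior 6), so components can be regenerated independently.
#' @param genome `data.frame(chrom, length)` of the toy genome.
#' @param n_genes,gene_length,exons_per_gene,exon_length Gene-model shape.
#' @param n_background_peaks Peaks shared by every condition.
#' @param n_gained,n_lost Planted differential regions per stress
#'   condition.
#' @param shared_fraction Fraction of each planted set shared between the
#'   susceptible and resilient conditions (drives condition-specific
#'   subtraction).
#' @param n_replicates Peak-set replicates per condition.
#' @param peak_width Nominal peak width in bp.
#' @param jitter_sd Per-replicate Gaussian boundary jitter SD in bp.
#' @param dropout Per-replicate dropout probability for background peaks;
#'   planted regions are never dropped.
#' @param slot_spacing Spacing of candidate peak slots in bp; keeps
#'   distinct planted regions well beyond the overlap window.
#' @param intergenic_fraction Fraction of peaks placed outside genes.
#' @param count_replicates Samples per group in the count simulation.
#' @param base_cpm Baseline region abundance in counts per million.
#' @param planted_fold True stress/control abundance ratio at planted
#'   regions.
#' @param nb_dispersion Negative-binomial dispersion (`size = 1/disp`).
#' @param library_size_range Range mapped reads are drawn from.
#' @param p_up_given_gain,p_down_given_loss Probability that a gene
#'   hosting a gained (lost) region is transcriptionally up (down).
#' @param expr_effect_mean,expr_effect_sd,expr_null_sd Expression effect
#'   magnitude distribution and null SD.
#' @param temporal_group_counts Named counts of planted trajectory groups.
#' @param temporal_epsilon,temporal_noise_sd,matched_fraction Temporal
#'   dead zone, additive LFC noise SD, and fraction of profiles with
#'   matching expression trajectories.
#' @param n_control_animals,n_stress_animals,p_resilient,n_exclusion_records
#'   Behavioral cohort sizes, resilient proportion among stressed, and
#'   number of injected exclusion-triggering records.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
  seed = 1,
  genome = data.frame(chrom = c("chr1", "chr2"),
                      length = c(1200000L, 800000L),
                      stringsAsFactors = FALSE),
  n_genes = 160, gene_length = 8000L, exons_per_gene = 3, exon_length = 600L,
  n_background_peaks = 200, n_gained = 40, n_lost = 25,
  shared_fraction = 0.3,
  n_replicates = 3, peak_width = 300L, jitter_sd = 30, dropout = 0.05,
  slot_spacing = 2000L, intergenic_fraction = 0.2,
  count_replicates = 6, base_cpm = 50, planted_fold = 2,
  nb_dispersion = 0.2, library_size_range = c(8e5, 1.2e6),
  p_up_given_gain = 0.40, p_down_given_loss = 0.58,
  expr_effect_mean = 0.5, expr_effect_sd = 0.2, expr_null_sd = 0.1,
  temporal_group_counts = c(I = 250, II = 250, III = 250, IV = 250),
  temporal_epsilon = 0.1, temporal_noise_sd = 0.05, matched_fraction = 0.5,
  n_control_animals = 20, n_stress_animals = 200, p_resilient = 0.2,
  n_exclusion_records = 2
) {
  cfg <- as.list(environment())
  probs <- c(shared_fraction, dropout, intergenic_fraction,
             p_up_given_gain, p_down_given_loss, matched_fraction,
             p_resilient)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(n_genes, n_background_peaks, n_gained, n_lost, n_replicates,
              count_replicates, temporal_group_counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(genome$length <= 0)) stop("chromosome lengths must be positive")
  class(cfg) <- "sim_config"
  cfg
}

child_seed <- function(seed, stage) {
  (as.integer(seed) + 97L * as.integer(stage)) %% 2147483629L
}

#' Simulate a toy genome's gene model
#'
#' Genes are laid out in disjoint, evenly spaced bins per chromosome
#' (count proportional to chromosome length), with uniform start offsets
#' within each bin, random strands, and evenly spaced exons. Deterministic
#' for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return A `GeneModel`.
#' @export
simulate_genome_and_genes <- function(cfg) {
  set.seed(child_seed(cfg$seed, 1))
  gn <- cfg$genome
  if (cfg$n_genes == 0) {
    return(gene_model(
      data.frame(gene_id = character(0), symbol = character(0),
                 chrom = character(0), strand = character(0),
                 tx_start = integer(0), tx_end = integer(0)),
      data.frame(gene_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0)),
      gn))
  }
  n_per <- round(cfg$n_genes * gn$length / sum(gn$length))
  n_per[1] <- n_per[1] + (cfg$n_genes - sum(n_per))
  genes <- NULL; exons <- NULL; gi <- 0L
  for (ci in seq_len(nrow(gn))) {
    nc <- n_per[ci]
    if (nc == 0) next
    bin <- floor(gn$length[ci] / nc)
    if (bin < cfg$gene_length + 200L)
      stop("genes cannot fit: reduce n_genes or gene_length, ",
           "or enlarge the genome")
    for (k in seq_len(nc)) {
      gi <- gi + 1L
      slack <- bin - cfg$gene_length - 100L
      s <- (k - 1L) * bin + 50L + sample.int(slack, 1L)
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("G%04d", gi), symbol = sprintf("Gene%04d", gi),
        chrom = gn$chrom[ci], strand = sample(c("+", "-"), 1L),
        tx_start = s, tx_end = s + cfg$gene_length,
        stringsAsFactors = FALSE))
      seg <- floor(cfg$gene_length / cfg$exons_per_gene)
      for (e in seq_len(cfg$exons_per_gene)) {
        es <- s + (e - 1L) * seg
        exons <- rbind(exons, data.frame(
          gene_id = sprintf("G%04d", gi), chrom = gn$chrom[ci],
          start = es, end = es + min(cfg$exon_length, seg),
          stringsAsFactors = FALSE))
      }
    }
  }
  gene_model(genes, exons, gn)
}

# Candidate peak slots on a regular grid, classified genic/intergenic by
# whether the peak midpoint falls inside a gene span. `body` marks slots
# deep inside the host gene (clear of the promoter/termination windows);
# `nearest_ok` marks genic slots whose nearest-TSS gene is the host, so
# that planted effects annotate back to the gene they were planted in.
peak_slots <- function(cfg, model, body_margin = 1500L) {
  gn <- cfg$genome
  slots <- NULL
  for (ci in seq_len(nrow(gn))) {
    starts <- seq(1000L, gn$length[ci] - cfg$slot_spacing,
                  by = cfg$slot_spacing)
    slots <- rbind(slots, data.frame(chrom = gn$chrom[ci],
                                     start = as.integer(starts),
                                     stringsAsFactors = FALSE))
  }
  slots$end <- slots$start + cfg$peak_width
  mid <- (slots$start + slots$end) %/% 2L
  g <- model$genes
  genic <- rep(FALSE, nrow(slots))
  host <- rep(NA_character_, nrow(slots))
  body <- rep(FALSE, nrow(slots))
  for (i in seq_len(nrow(g))) {
    inside <- slots$chrom == g$chrom[i] & mid >= g$tx_start[i] &
      mid < g$tx_end[i]
    genic[inside] <- TRUE
    host[inside] <- g$gene_id[i]
    body[slots$chrom == g$chrom[i] & mid >= g$tx_start[i] + body_margin &
           mid < g$tx_end[i] - body_margin] <- TRUE
  }
  slots$genic <- genic
  slots$gene_id <- host
  slots$body <- body
  nearest_ok <- rep(FALSE, nrow(slots))
  if (nrow(g) > 0 && any(genic)) {
    gi <- which(genic)
    ids <- sprintf("slot%06d", gi)
    ng <- nearest_gene(g_intervals(slots$chrom[gi], slots$start[gi],
                                   slots$end[gi], id = ids),
                       model)
    near <- ng$gene_id[match(ids, ng$id)]
    nearest_ok[gi[near == host[gi]]] <- TRUE
  }
  slots$nearest_ok <- nearest_ok
  slots
}

#' Simulate per-replicate peak collections with planted differentials
#'
#' Plants, on a slot grid whose spacing far exceeds the overlap window:
#' background peaks (present in susceptible, resilient and control),
#' gained peaks (present only in one or both stress conditions), and lost
#' peaks (absent from one or both stress conditions). Each replicate adds
#' independent Gaussian boundary jitter; background peaks are dropped per
#' replicate index with the configured probability (the same weak regions
#' fail peak calling in the matched technical replicate of every
#' condition, so presence/absence differences reflect only planted
#' biology); planted regions are never dropped.
#'
#' @param cfg A [sim_config()].
#' @param model The [simulate_genome_and_genes()] output.
#' @param mark Modification mark to stamp on the collections.
#' @return `list(replicates, truth)`: `replicates` is a nested list
#'   `[[condition]][[replicate]]` of `PeakCollection`s (conditions
#'   `susceptible`, `resilient`, `control`); `truth` is a `data.frame`
#'   (id, chrom, start, end, role, genic, gene_id) where role is one of
#'   `background`, `gain_sus`, `gain_res`, `gain_shared`, `loss_sus`,
#'   `loss_res`, `loss_shared`.
#' @export
simulate_peaks <- function(cfg, model, mark = "5mC") {
  set.seed(child_seed(cfg$seed, 2))
  slots <- peak_slots(cfg, model)
  n_gain_shared <- round(cfg$shared_fraction * cfg$n_gained)
  n_gain_only <- cfg$n_gained - n_gain_shared
  n_loss_shared <- round(cfg$shared_fraction * cfg$n_lost)
  n_loss_only <- cfg$n_lost - n_loss_shared
  roles <- c(rep("background", cfg$n_background_peaks),
             rep("gain_sus", n_gain_only), rep("gain_res", n_gain_only),
             rep("gain_shared", n_gain_shared),
             rep("loss_sus", n_loss_only), rep("loss_res", n_loss_only),
             rep("loss_shared", n_loss_shared))
  n_total <- length(roles)
  planted <- roles != "background"
  n_planted <- sum(planted)
  n_bg <- n_total - n_planted
  n_planted_genic <- round((1 - cfg$intergenic_fraction) * n_planted)
  n_bg_genic <- round((1 - cfg$intergenic_fraction) * n_bg)
  # planted genic effects sit in gene bodies, one per host gene, at slots
  # whose nearest-TSS gene is the host: the planted gene-level truth then
  # coincides with what annotation recovers
  cand <- which(slots$genic & slots$body & slots$nearest_ok)
  cand <- cand[sample(length(cand))]
  cand <- cand[!duplicated(slots$gene_id[cand])]
  if (length(cand) < n_planted_genic)
    stop("not enough distinct gene-body slots for planted effects; ",
         "enlarge the genome or raise n_genes")
  planted_genic <- cand[seq_len(n_planted_genic)]
  genic_rest <- setdiff(which(slots$genic), planted_genic)
  inter_pool <- which(!slots$genic)
  n_inter_needed <- (n_planted - n_planted_genic) + (n_bg - n_bg_genic)
  if (length(genic_rest) < n_bg_genic ||
      length(inter_pool) < n_inter_needed)
    stop("not enough peak slots; enlarge the genome or reduce peak counts")
  shuf <- function(x) x[sample.int(length(x))]
  draw <- function(x, k) x[sample.int(length(x), k)]
  inter_chosen <- draw(inter_pool, n_inter_needed)
  n_planted_inter <- n_planted - n_planted_genic
  planted_slots <- shuf(c(planted_genic,
                          inter_chosen[seq_len(n_planted_inter)]))
  bg_slots <- shuf(c(draw(genic_rest, n_bg_genic),
                     inter_chosen[setdiff(seq_len(n_inter_needed),
                                          seq_len(n_planted_inter))]))
  chosen <- integer(n_total)
  chosen[planted] <- planted_slots
  chosen[!planted] <- bg_slots
  truth <- slots[chosen, , drop = FALSE]
  truth$role <- roles
  truth$id <- sprintf("peak%04d", seq_len(n_total))
  rownames(truth) <- NULL
  truth <- truth[, c("id", "chrom", "start", "end", "role", "genic",
                     "gene_id")]

  membership <- list(
    susceptible = c("background", "gain_sus", "gain_shared", "loss_res"),
    resilient = c("background", "gain_res", "gain_shared", "loss_sus"),
    control = c("background", "loss_sus", "loss_res", "loss_shared")
  )
  # condition-symmetric dropout indicators: peak x replicate index
  drop_mat <- matrix(FALSE, n_total, cfg$n_replicates)
  bg <- truth$role == "background"
  drop_mat[bg, ] <- stats::runif(sum(bg) * cfg$n_replicates) < cfg$dropout

  clen <- cfg$genome$length[match(truth$chrom, cfg$genome$chrom)]
  replicates <- list()
  for (cond in names(membership)) {
    in_cond <- truth$role %in% membership[[cond]]
    reps <- list()
    for (r in seq_len(cfg$n_replicates)) {
      keep <- in_cond & !drop_mat[, r]
      s <- truth$start[keep] +
        round(stats::rnorm(sum(keep), 0, cfg$jitter_sd))
      e <- truth$end[keep] + round(stats::rnorm(sum(keep), 0, cfg$jitter_sd))
      s <- pmax(s, 0L)
      e <- pmax(e, s + 50L)
      e <- pmin(e, clen[keep])
      reps[[r]] <- peak_collection(
        g_intervals(truth$chrom[keep], s, e, id = truth$id[keep]),
        sample_id = sprintf("%s_rep%d", cond, r), mark = mark,
        condition = if (cond == "control") "control" else cond,
        paradigm = "CSDS", age = "3mo")
    }
    replicates[[cond]] <- reps
  }
  list(replicates = replicates, truth = truth)
}

#' Simulate negative-binomial region counts and a library manifest
#'
#' `raw[i, j] ~ NB(mean = base_cpm * fold(i, condition_j) *
#' library_size_j / 1e6, dispersion)`. Planted gained regions carry the
#' configured fold in stress; planted lost regions carry it in control.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [simulate_peaks()] (or any
#'   `data.frame(id, chrom, start, end, role)`).
#' @param stress_roles Roles counted as elevated in stress (default: the
#'   susceptible-condition gains).
#' @param loss_roles Roles elevated in control.
#' @return List: `regions` (interval table), `raw` (matrix),
#'   `manifest` (`data.frame(sample_id, mapped_reads, condition,
#'   replicate)`), `true_fold` (per-region stress:control ratio).
#' @export
simulate_counts <- function(cfg, truth,
                            stress_roles = c("gain_sus", "gain_shared"),
                            loss_roles = c("loss_sus", "loss_shared")) {
  set.seed(child_seed(cfg$seed, 3))
  nr <- nrow(truth)
  mult_stress <- ifelse(truth$role %in% stress_roles, cfg$planted_fold, 1)
  mult_control <- ifelse(truth$role %in% loss_roles, cfg$planted_fold, 1)
  fold <- mult_stress / mult_control
  n <- cfg$count_replicates
  manifest <- data.frame(
    sample_id = c(sprintf("stress_s%d", seq_len(n)),
                  sprintf("control_s%d", seq_len(n))),
    mapped_reads = round(stats::runif(2 * n, cfg$library_size_range[1],
                                      cfg$library_size_range[2])),
    condition = rep(c("stress", "control"), each = n),
    replicate = rep(seq_len(n), 2),
    stringsAsFactors = FALSE)
  raw <- matrix(0L, nr, 2 * n,
                dimnames = list(truth$id, manifest$sample_id))
  for (j in seq_len(2 * n)) {
    f <- if (manifest$condition[j] == "stress") mult_stress else mult_control
    mu <- cfg$base_cpm * f * manifest$mapped_reads[j] / 1e6
    raw[, j] <- stats::rnbinom(nr, mu = mu, size = 1 / cfg$nb_dispersion)
  }
  regions <- g_intervals(truth$chrom, truth$start, truth$end, id = truth$id)
  # region sorting must not detach ids from matrix rows
  raw <- raw[match(regions$id, truth$id), , drop = FALSE]
  true_fold <- fold[match(regions$id, truth$id)]
  list(regions = regions, raw = raw, manifest = manifest,
       true_fold = true_fold)
}

#' Simulate expression fold changes correlated with planted modifications
#'
#' Of the genes hosting a gained region, an exactly `round(p * n)`-sized
#' random subset is upregulated (magnitude `|N(0.5, 0.2)|`) at rate
#' `p_up_given_gain`, the rest down; symmetrically, loss-hosting genes are
#' downregulated at rate `p_down_given_loss`; all other genes draw null
#' `N(0, 0.1)` fold changes. Exact-count planting realizes the configured
#' conditional rates for every seed.
#'
#' @param cfg A [sim_config()].
#' @param model The `GeneModel`.
#' @param truth Truth table from [simulate_peaks()].
#' @param gain_roles,loss_roles Which planted roles count as gained/lost
#'   for the contrast being expressed.
#' @param stage_offset Added to the child-seed stage so independent
#'   tables (e.g. two ages) can be drawn.
#' @return `list(expression, truth)`: `expression` is a
#'   `data.frame(gene_id, symbol, expr_lfc, q_value)`; `truth` maps
#'   gene_id to its planted expression category
#'   (`up`, `down`, `null`).
#' @export
simulate_expression <- function(cfg, model, truth,
                                gain_roles = c("gain_sus", "gain_shared"),
                                loss_roles = c("loss_sus", "loss_shared"),
                                stage_offset = 0) {
  set.seed(child_seed(cfg$seed, 4 + stage_offset))
  g <- model$genes
  gain_genes <- unique(stats::na.omit(
    truth$gene_id[truth$role %in% gain_roles]))
  loss_genes <- unique(stats::na.omit(
    truth$gene_id[truth$role %in% loss_roles]))
  loss_genes <- setdiff(loss_genes, gain_genes)  # gain wins rare conflicts
  lfc <- stats::rnorm(nrow(g), 0, cfg$expr_null_sd)
  cat_ <- rep("null", nrow(g))
  eff <- function(k) abs(stats::rnorm(k, cfg$expr_effect_mean,
                                      cfg$expr_effect_sd))
  # exact-count planting: exactly round(p * n) hosts draw the concordant
  # sign, assigned to a uniformly random subset, so the configured rates
  # are realized exactly (up to rounding) for every seed
  plant <- function(k, p) {
    hits <- rep(c(TRUE, FALSE), c(round(p * k), k - round(p * k)))
    hits[sample.int(k)]
  }
  ig <- match(gain_genes, g$gene_id)
  up <- plant(length(ig), cfg$p_up_given_gain)
  lfc[ig] <- ifelse(up, 1, -1) * eff(length(ig))
  cat_[ig] <- ifelse(up, "up", "down")
  il <- match(loss_genes, g$gene_id)
  down <- plant(length(il), cfg$p_down_given_loss)
  lfc[il] <- ifelse(down, -1, 1) * eff(length(il))
  cat_[il] <- ifelse(down, "down", "up")
  list(
    expression = data.frame(gene_id = g$gene_id, symbol = g$symbol,
                            expr_lfc = lfc, q_value = NA_real_,
                            stringsAsFactors = FALSE),
    truth = data.frame(gene_id = g$gene_id, category = cat_,
                       hosts_gain = g$gene_id %in% gain_genes,
                       hosts_loss = g$gene_id %in% loss_genes,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate temporal trajectory profiles with planted group labels
#'
#' Each profile draws a baseline acute fold change, then steps by signed
#' margins of at least `3 * epsilon` according to its planted group's
#' delta-sign pattern; independent Gaussian noise of SD
#' `temporal_noise_sd` is added to each of the three values. A
#' `matched_fraction` share of profiles receives an expression trajectory
#' with the same delta-sign pattern; the rest get flat expression.
#'
#' @param cfg A [sim_config()].
#' @return `list(profiles, truth)`: `profiles` has the six fold changes
#'   per region id; `truth` the planted `group` and `matched` flag.
#' @export
simulate_temporal <- function(cfg) {
  set.seed(child_seed(cfg$seed, 5))
  counts <- cfg$temporal_group_counts
  eps <- cfg$temporal_epsilon
  pattern <- list(I = c(1, 1), II = c(-1, -1), III = c(1, -1),
                  IV = c(-1, 1))
  n <- sum(counts)
  group <- rep(names(counts), counts)
  s1 <- vapply(group, function(gp) pattern[[gp]][1], numeric(1))
  s2 <- vapply(group, function(gp) pattern[[gp]][2], numeric(1))
  margin <- function() 3 * eps + stats::runif(n, 0, 0.3)
  a <- stats::rnorm(n, 0, 0.3)
  cc <- a + s1 * margin()
  l <- cc + s2 * margin()
  noise <- function() stats::rnorm(n, 0, cfg$temporal_noise_sd)
  lfc_A <- a + noise(); lfc_C <- cc + noise(); lfc_L <- l + noise()
  n_match <- round(cfg$matched_fraction * n)
  matched <- rep(c(TRUE, FALSE), c(n_match, n - n_match))[sample.int(n)]
  ea <- stats::rnorm(n, 0, 0.3)
  ec <- ea + s1 * margin(); el <- ec + s2 * margin()
  expr_A <- ifelse(matched, ea + noise(), ea)
  expr_C <- ifelse(matched, ec + noise(), ea)
  expr_L <- ifelse(matched, el + noise(), ea)
  ids <- sprintf("tprof%04d", seq_len(n))
  list(
    profiles = data.frame(id = ids, lfc_A = lfc_A, lfc_C = lfc_C,
                          lfc_L = lfc_L, expr_A = expr_A, expr_C = expr_C,
                          expr_L = expr_L, stringsAsFactors = FALSE),
    truth = data.frame(id = ids, group = group, matched = matched,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a behavioral cohort
#'
#' Stressed animals are resilient with probability `p_resilient` (drawn
#' with a planted SIR at or above 1), susceptible otherwise (SIR below 1);
#' controls draw SIRs at or above 1. Interaction times are drawn so the
#' ratio reproduces the planted SIR exactly, and a configurable number of
#' exclusion-triggering records (no-target time under 1 s; SIR above 300)
#' is appended.
#'
#' @param cfg A [sim_config()].
#' @return `list(records, truth)`: `records` is the raw cohort table
#'   (`animal_id`, `group`, `t_target`, `t_no_target`, `sucrose_g`,
#'   `water_g`), `truth` the planted phenotype per animal
#'   (`control`, `susceptible`, `resilient`, `excluded`).
#' @export
simulate_behavior <- function(cfg) {
  set.seed(child_seed(cfg$seed, 6))
  n_c <- cfg$n_control_animals; n_s <- cfg$n_stress_animals
  n_res <- round(cfg$p_resilient * n_s)
  resil <- rep(c(TRUE, FALSE), c(n_res, n_s - n_res))[sample.int(n_s)]
  sir_s <- ifelse(resil, stats::runif(n_s, 1.01, 2.5),
                  stats::runif(n_s, 0.2, 0.99))
  sir_c <- stats::runif(n_c, 1.0, 2.5)
  pref <- c(stats::runif(n_c, 65, 90),
            ifelse(resil, stats::runif(n_s, 60, 85),
                   stats::runif(n_s, 40, 70)))
  t_no <- stats::runif(n_c + n_s, 30, 90)
  sir <- c(sir_c, sir_s)
  total <- stats::runif(n_c + n_s, 3, 6)
  records <- data.frame(
    animal_id = sprintf("A%03d", seq_len(n_c + n_s)),
    group = rep(c("control", "stress"), c(n_c, n_s)),
    t_target = sir * t_no, t_no_target = t_no,
    sucrose_g = pref / 100 * total, water_g = (1 - pref / 100) * total,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    animal_id = records$animal_id,
    phenotype = c(rep("control", n_c),
                  ifelse(resil, "resilient", "susceptible")),
    stringsAsFactors = FALSE)
  if (cfg$n_exclusion_records > 0) {
    k <- cfg$n_exclusion_records
    # alternate the two exclusion triggers
    low <- seq_len(k) %% 2 == 1
    extra <- data.frame(
      animal_id = sprintf("X%03d", seq_len(k)),
      group = "stress",
      t_target = ifelse(low, 30, 400),
      t_no_target = ifelse(low, 0.5, 1.2),
      sucrose_g = 2, water_g = 2, stringsAsFactors = FALSE)
    records <- rbind(records, extra)
    truth <- rbind(truth, data.frame(animal_id = extra$animal_id,
                                     phenotype = "excluded",
                                     stringsAsFactors = FALSE))
  }
  list(records = records, truth = truth)
}

#' Generate the full synthetic input bundle on disk
#'
#' Writes every file the pipeline consumes — gene model GTF, chromosome
#' sizes, per-replicate peak BEDs per condition, region count TSV with a
#' library manifest, expression TSVs (two ages), temporal profile TSV,
#' behavior CSV — plus `truth.json` holding the planted ground truth
#' (kept out of all data files). Byte-identical for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`model`, `peaks`,
#'   `counts`, `expression`, `expression_6mo`, `temporal`, `behavior`)
#'   and the file manifest.
#' @export
simulate_all <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  model <- simulate_genome_and_genes(cfg)
  write_gene_model_gtf(model, p("genes.gtf"))
  utils::write.table(cfg$genome, p("genome.chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  peaks <- simulate_peaks(cfg, model)
  for (cond in names(peaks$replicates)) {
    for (r in seq_along(peaks$replicates[[cond]])) {
      write_bed(peaks$replicates[[cond]][[r]]$intervals,
                p(sprintf("peaks_%s_rep%d.bed", cond, r)))
    }
  }
  counts <- simulate_counts(cfg, peaks$truth)
  ct <- data.frame(region_id = counts$regions$id,
                   chrom = counts$regions$chrom,
                   start = counts$regions$start, end = counts$regions$end,
                   stringsAsFactors = FALSE)
  ct <- cbind(ct, as.data.frame(counts$raw, stringsAsFactors = FALSE))
  write_tsv(ct, p("region_counts.tsv"))
  write_tsv(counts$manifest, p("library_manifest.tsv"))
  expr3 <- simulate_expression(cfg, model, peaks$truth)
  expr6 <- simulate_expression(cfg, model, peaks$truth, stage_offset = 20)
  for (nm in c("3mo", "6mo")) {
    ex <- if (nm == "3mo") expr3 else expr6
    df <- data.frame(gene_id = ex$expression$gene_id,
                     symbol = ex$expression$symbol,
                     log2fc = ex$expression$expr_lfc,
                     q_value = ex$expression$q_value,
                     stringsAsFactors = FALSE)
    write_tsv(df, p(sprintf("expression_%s.tsv", nm)))
  }
  temporal <- simulate_temporal(cfg)
  write_tsv(temporal$profiles, p("temporal_profiles.tsv"))
  behavior <- simulate_behavior(cfg)
  utils::write.csv(behavior$records, p("behavior.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- list(peaks = peaks$truth, expression_3mo = expr3$truth,
                expression_6mo = expr6$truth, temporal = temporal$truth,
                behavior = behavior$truth,
                params = cfg[setdiff(names(cfg), "genome")])
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, peaks = peaks, counts = counts,
                 expression = expr3, expression_6mo = expr6,
                 temporal = temporal, behavior = behavior,
                 dir = outdir))
}
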