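#' Classify differential-region genes by concomitant expression change
#'
#' A gene linked to a gained region whose expression log2 fold change is
#' positive is *concomitantly increasing*; a gene linked to a lost region
#' with negative expression change is *concomitantly decreasing*;
#' everything else (including an expression change of exactly 0) is
#' *nonconcomitant*. Genes absent from the expression table are returned
#' separately as unmatched, not silently dropped.
#'
#' @param diff_genes `data.frame` with at least `gene_id`, `symbol`,
#'   `direction` (`"gained"`/`"lost"`) and optionally `id` (region id),
#'   `mark`, `mod_lfc` — typically annotated differential regions after
#'   [drop_intergenic()].
#' @param expression Expression table with unique `gene_id` rows and
#'   finite `expr_lfc` (see [read_expression_table()]).
#' @return `list(classified, unmatched)`; `classified` adds `expr_lfc` and
#'   `class` (`concomitant_increase` / `concomitant_decrease` /
#'   `nonconcomitant`) to the matched rows.
#' @export
classify_concomitant <- function(diff_genes, expression) {
  stopifnot(all(c("gene_id", "direction") %in% names(diff_genes)),
            all(diff_genes$direction %in% c("gained", "lost")))
  if (anyDuplicated(expression$gene_id))
    stop("duplicate gene rows in expression table")
  idx <- match(diff_genes$gene_id, expression$gene_id)
  matched <- !is.na(idx)
  out <- diff_genes[matched, , drop = FALSE]
  out$expr_lfc <- expression$expr_lfc[idx[matched]]
  out$class <- ifelse(out$direction == "gained" & out$expr_lfc > 0,
                      "concomitant_increase",
               ifelse(out$direction == "lost" & out$expr_lfc < 0,
                      "concomitant_decrease", "nonconcomitant"))
  rownames(out) <- NULL
  unmatched <- diff_genes[!matched, , drop = FALSE]
  rownames(unmatched) <- NULL
  list(classified = out, unmatched = unmatched)
}

#' Concomitance fractions and concomitant:nonconcomitant ratio
#'
#' @param genes Classified gene table from [classify_concomitant()].
#' @return List: `fraction_increase_given_gain` (share of gained-region
#'   genes that concomitantly increase), `fraction_decrease_given_loss`,
#'   their denominators `n_gained`/`n_lost`, and `ratio_concomitant`
#'   (concomitant / nonconcomitant gene count; `Inf` when every gene is
#'   concomitant). Empty input is an error; an empty direction stratum
#'   reports `NA` rather than 0.
#' @export
concomitance_fraction <- function(genes) {
  if (nrow(genes) == 0) stop("no classified genes supplied")
  gained <- genes[genes$direction == "gained", , drop = FALSE]
  lost <- genes[genes$direction == "lost", , drop = FALSE]
  frac <- function(x, cls) if (nrow(x) == 0) NA_real_
                           else mean(x$class == cls)
  n_con <- sum(genes$class != "nonconcomitant")
  list(
    fraction_increase_given_gain = frac(gained, "concomitant_increase"),
    fraction_decrease_given_loss = frac(lost, "concomitant_decrease"),
    n_gained = nrow(gained), n_lost = nrow(lost),
    ratio_concomitant = n_con / (nrow(genes) - n_con)
  )
}

#' Remove genes shared between a gain list and a loss list
#'
#' A gene appearing in both the gain and the loss list of the same
#' phenotype has an ambiguous modification direction and is removed from
#' both; within-list duplicates are collapsed to one entry. The returned
#' lists are disjoint.
#'
#' @param gain,loss Character vectors of gene identifiers (or symbols).
#' @return `list(gain, loss)` of deduplicated, disjoint vectors (input
#'   order of first occurrence preserved).
#' @export
dedup_genes <- function(gain, loss) {
  gain <- unique(gain)
  loss <- unique(loss)
  both <- intersect(gain, loss)
  list(gain = setdiff(gain, both), loss = setdiff(loss, both))
}

#' Filter top candidate genes by direction-consistent expression change at
#' both ages
#'
#' A gained-region gene is retained when its expression log2 fold change
#' exceeds `threshold` at both 3 and 6 months; a lost-region gene when it
#' is below `-threshold` at both. Genes missing from either age table are
#' excluded and reported.
#'
#' @param genes `data.frame(gene_id, direction)` (plus any carried
#'   columns); one row per gene/direction.
#' @param expr_3mo,expr_6mo Expression tables for the two ages.
#' @param threshold Strict log2 fold-change cutoff (default 0.25).
#' @return `list(retained, missing)`: `retained` adds `expr_lfc_3mo` and
#'   `expr_lfc_6mo`; `missing` lists gene ids absent from an age table.
#' @export
top_candidates <- function(genes, expr_3mo, expr_6mo, threshold = 0.25) {
  i3 <- match(genes$gene_id, expr_3mo$gene_id)
  i6 <- match(genes$gene_id, expr_6mo$gene_id)
  present <- !is.na(i3) & !is.na(i6)
  missing <- genes$gene_id[!present]
  g <- genes[present, , drop = FALSE]
  g$expr_lfc_3mo <- expr_3mo$expr_lfc[i3[present]]
  g$expr_lfc_6mo <- expr_6mo$expr_lfc[i6[present]]
  keep <- ifelse(g$direction == "gained",
                 g$expr_lfc_3mo > threshold & g$expr_lfc_6mo > threshold,
                 g$expr_lfc_3mo < -threshold & g$expr_lfc_6mo < -threshold)
  retained <- g[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, missing = missing)
}

#' Case-insensitive overlap with an external gene-symbol list
#'
#' @param symbols Character vector of gene symbols (e.g. the package's
#'   candidate genes).
#' @param external Character vector of symbols from a published list; an
#'   empty list raises a warning and yields an empty overlap.
#' @return `list(overlap, n_input, n_list, n_overlap)`; `overlap` keeps the
#'   input's original casing, duplicates collapsed.
#' @export
gene_list_overlap <- function(symbols, external) {
  if (length(external) == 0)
    warning("external gene list is empty; overlap is empty")
  symbols <- unique(symbols)
  hit <- tolower(symbols) %in% tolower(unique(external))
  list(overlap = symbols[hit],
       n_input = length(symbols),
       n_list = length(unique(tolower(external))),
       n_overlap = sum(hit))
}
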