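# Sign with a dead zone: +1 above eps, -1 below -eps, 0 within.
sign_eps <- function(x, eps) {
  ifelse(x > eps, 1L, ifelse(x < -eps, -1L, 0L))
}

#' Classify modification trajectories across the acute-chronic-longitudinal
#' stress time course
#'
#' With between-stage deltas `d1 = lfc_C - lfc_A` and `d2 = lfc_L - lfc_C`
#' and a dead zone `epsilon`:
#' Group `I` (continual gain) when both deltas exceed `epsilon`;
#' Group `II` (continual loss) when both fall below `-epsilon`;
#' Group `III` (gain then loss) when `d1 > epsilon` and `d2 < -epsilon`;
#' Group `IV` (loss then gain) when `d1 < -epsilon` and `d2 > epsilon`;
#' anything else is `unclassified`. Classification depends only on the
#' deltas, so adding a constant to all three values never changes a label.
#'
#' @param lfc_A,lfc_C,lfc_L Numeric vectors: per-paradigm modification
#'   log2 fold changes (each stress paradigm vs its own matched control)
#'   for acute, chronic and longitudinal defeat.
#' @param epsilon Dead-zone half-width on the delta scale (default 0.1);
#'   `epsilon = 0` reduces to pure sign logic.
#' @param require_baseline If `TRUE`, the return-to-baseline groups III/IV
#'   additionally require `|lfc_L| <= epsilon` (stricter reading of
#'   "return to baseline"); default `FALSE`.
#' @return Character vector in
#'   `c("I", "II", "III", "IV", "unclassified")`.
#' @export
classify_trajectory <- function(lfc_A, lfc_C, lfc_L, epsilon = 0.1,
                                require_baseline = FALSE) {
  if (any(!is.finite(c(lfc_A, lfc_C, lfc_L))))
    stop("all log2 fold changes must be finite")
  if (epsilon < 0) stop("epsilon must be >= 0")
  s1 <- sign_eps(lfc_C - lfc_A, epsilon)
  s2 <- sign_eps(lfc_L - lfc_C, epsilon)
  grp <- rep("unclassified", length(s1))
  grp[s1 == 1L & s2 == 1L] <- "I"
  grp[s1 == -1L & s2 == -1L] <- "II"
  grp[s1 == 1L & s2 == -1L] <- "III"
  grp[s1 == -1L & s2 == 1L] <- "IV"
  if (require_baseline) {
    back <- grp %in% c("III", "IV") & abs(lfc_L) > epsilon
    grp[back] <- "unclassified"
  }
  grp
}

#' Does the expression trajectory match the modification trajectory?
#'
#' True when the expression deltas share the (dead-zoned) sign pattern of
#' the modification deltas at both transitions — e.g. both the
#' modification and the expression rose from acute to chronic and fell
#' from chronic to longitudinal.
#'
#' @param lfc_A,lfc_C,lfc_L Modification log2 fold changes per paradigm.
#' @param expr_A,expr_C,expr_L Expression log2 fold changes per paradigm.
#' @param epsilon Dead zone applied to both delta scales (default 0.1).
#' @return Logical vector.
#' @export
match_expression <- function(lfc_A, lfc_C, lfc_L, expr_A, expr_C, expr_L,
                             epsilon = 0.1) {
  sign_eps(expr_C - expr_A, epsilon) == sign_eps(lfc_C - lfc_A, epsilon) &
    sign_eps(expr_L - expr_C, epsilon) == sign_eps(lfc_L - lfc_C, epsilon)
}

#' Build temporal profiles with group labels and expression matching
#'
#' Convenience wrapper combining [classify_trajectory()] and
#' [match_expression()] over parallel vectors.
#'
#' @param ids Region (or gene) identifiers.
#' @param lfc_A,lfc_C,lfc_L Modification log2 fold changes.
#' @param expr_A,expr_C,expr_L Expression log2 fold changes.
#' @param epsilon Dead zone (default 0.1).
#' @param require_baseline Passed to [classify_trajectory()].
#' @return `data.frame` with all six fold changes, `group` and
#'   `expression_matched`.
#' @export
temporal_profiles <- function(ids, lfc_A, lfc_C, lfc_L,
                              expr_A, expr_C, expr_L, epsilon = 0.1,
                              require_baseline = FALSE) {
  data.frame(
    id = ids,
    lfc_A = lfc_A, lfc_C = lfc_C, lfc_L = lfc_L,
    expr_A = expr_A, expr_C = expr_C, expr_L = expr_L,
    group = classify_trajectory(lfc_A, lfc_C, lfc_L, epsilon,
                                require_baseline),
    expression_matched = match_expression(lfc_A, lfc_C, lfc_L,
                                          expr_A, expr_C, expr_L, epsilon),
    stringsAsFactors = FALSE
  )
}

#' Categorize shared regions by fold-change direction at both ages
#'
#' Regions differential at both 3 and 6 months are split into those that
#' gained the modification at both ages (`gained_both`: both fold changes
#' positive), lost at both (`lost_both`), or changed direction
#' (`discordant`). Also reports the sign-concordance fraction.
#'
#' @param ids Region identifiers.
#' @param lfc_3mo,lfc_6mo Numeric vectors of log2 fold changes over the
#'   identical region list.
#' @return `list(categories, concordance)`: `categories` is a
#'   `data.frame(id, lfc_3mo, lfc_6mo, category)`, `concordance` the
#'   fraction of regions with sign-concordant fold changes.
#' @export
cross_age_categorize <- function(ids, lfc_3mo, lfc_6mo) {
  if (length(lfc_3mo) != length(lfc_6mo) || length(ids) != length(lfc_3mo))
    stop("ids, lfc_3mo and lfc_6mo must have equal length")
  category <- ifelse(lfc_3mo > 0 & lfc_6mo > 0, "gained_both",
              ifelse(lfc_3mo < 0 & lfc_6mo < 0, "lost_both", "discordant"))
  list(
    categories = data.frame(id = ids, lfc_3mo = lfc_3mo, lfc_6mo = lfc_6mo,
                            category = category, stringsAsFactors = FALSE),
    concordance = mean(category != "discordant")
  )
}
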