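#' Social interaction ratio
#'
#' Time spent in the interaction zone with the target divided by time
#' spent without the target. Records with zero no-target time cannot be
#' scored and return `NA` (such animals are removed by
#' [apply_exclusions()] before classification).
#'
#' @param t_target,t_no_target Seconds in the interaction zone with and
#'   without the target animal; non-negative.
#' @return Numeric vector of ratios (`NA` where `t_no_target == 0`).
#' @export
social_interaction_ratio <- function(t_target, t_no_target) {
  if (any(t_target < 0, na.rm = TRUE) || any(t_no_target < 0, na.rm = TRUE))
    stop("interaction times must be non-negative")
  ifelse(t_no_target > 0, t_target / t_no_target, NA_real_)
}

#' Classify stressed animals as susceptible or resilient
#'
#' Susceptible: SIR strictly below 1; resilient: SIR at or above 1 (the
#' boundary animal interacts as much with the target as without and is
#' called resilient).
#'
#' @param sir Numeric vector of social interaction ratios.
#' @return Character vector `"susceptible"`/`"resilient"` (`NA` in, `NA`
#'   out).
#' @export
classify_phenotype <- function(sir) {
  ifelse(is.na(sir), NA_character_,
         ifelse(sir < 1, "susceptible", "resilient"))
}

#' Apply social-interaction exclusion rules
#'
#' Animals with a no-target time under 1 s, or a SIR above 300, inflate
#' the ratio artificially and are removed; each exclusion carries its
#' reason.
#'
#' @param records `data.frame` with `t_target` and `t_no_target` columns
#'   (plus any others, carried through).
#' @return `list(retained, excluded)`; `excluded` gains an
#'   `exclusion_reason` column (`"no_target_lt_1s"` / `"sir_gt_300"`).
#' @export
apply_exclusions <- function(records) {
  sir <- social_interaction_ratio(records$t_target, records$t_no_target)
  low_time <- records$t_no_target < 1
  high_sir <- !is.na(sir) & sir > 300
  drop <- low_time | high_sir
  excluded <- records[drop, , drop = FALSE]
  excluded$exclusion_reason <- ifelse(low_time[drop], "no_target_lt_1s",
                                      "sir_gt_300")
  retained <- records[!drop, , drop = FALSE]
  rownames(retained) <- NULL
  rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Sucrose preference percentage
#'
#' `100 * sucrose / (sucrose + water)`; the percentage of total fluid
#' consumption that was sucrose solution. Zero total consumption yields
#' `NA` (no preference measurable).
#'
#' @param sucrose_g,water_g Grams of sucrose solution and water consumed;
#'   non-negative.
#' @return Numeric vector in `[0, 100]` (`NA` where total is 0).
#' @export
sucrose_preference <- function(sucrose_g, water_g) {
  if (any(sucrose_g < 0, na.rm = TRUE) || any(water_g < 0, na.rm = TRUE))
    stop("consumption masses must be non-negative")
  total <- sucrose_g + water_g
  ifelse(total > 0, 100 * sucrose_g / total, NA_real_)
}

#' Score a behavioral cohort table
#'
#' Applies two-scorer averaging (when `t_target_2`/`t_no_target_2` columns
#' are present, times are averaged before the ratio), the exclusion rules,
#' SIR computation, susceptibility classification (stressed animals only)
#' and sucrose preference.
#'
#' @param records `data.frame` with `animal_id`, `group`
#'   (`"control"`/`"stress"`), `t_target`, `t_no_target`, and optionally
#'   `sucrose_g`, `water_g`, and second-scorer time columns.
#' @return The input with added `sir`, `phenotype`, `excluded`,
#'   `exclusion_reason` and `sucrose_pref` columns; excluded animals keep
#'   their row but carry `NA` scores.
#' @export
score_behavior <- function(records) {
  stopifnot(all(c("animal_id", "group", "t_target", "t_no_target")
                %in% names(records)))
  if (all(c("t_target_2", "t_no_target_2") %in% names(records))) {
    records$t_target <- (records$t_target + records$t_target_2) / 2
    records$t_no_target <- (records$t_no_target + records$t_no_target_2) / 2
  }
  split <- apply_exclusions(records)
  out <- records
  out$sir <- social_interaction_ratio(out$t_target, out$t_no_target)
  out$excluded <- out$animal_id %in% split$excluded$animal_id
  out$exclusion_reason <- split$excluded$exclusion_reason[
    match(out$animal_id, split$excluded$animal_id)]
  out$sir[out$excluded] <- NA_real_
  out$phenotype <- ifelse(out$group == "stress" & !out$excluded,
                          classify_phenotype(out$sir), NA_character_)
  if (all(c("sucrose_g", "water_g") %in% names(records))) {
    out$sucrose_pref <- sucrose_preference(records$sucrose_g,
                                           records$water_g)
  }
  out
}
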