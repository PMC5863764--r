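# Scoring of the behavioral endpoints. "Recalled" always means the
# category response (object/scene) was correct; items misclassified in the
# object/scene categorisation task are excluded from all recall scoring,
# and cued/non-cued status is defined only among T1-correct items.

behavior_valid <- function(table) {
  if (anyDuplicated(paste(table$subject, table$item_id)) > 0)
    stop("behavior: duplicate item keys")
  table[table$categorisation_correct, , drop = FALSE]
}

cond_rows <- function(tab, condition) {
  switch(condition,
         cued = tab[isTRUE_vec(tab$cued), , drop = FALSE],
         noncued = tab[!is.na(tab$cued) & !tab$cued, , drop = FALSE],
         all = tab,
         stop("behavior: unknown condition ", condition))
}

#' Conditional retention proportion
#'
#' Proportion of items recalled at test `from` that are also recalled at
#' test `to`, within one subject and condition. Returns NA (flagged by a
#' warning) when the denominator is empty.
#'
#' @param table a `nap_behavior` table for one subject.
#' @param from,to test phases, e.g. `"t2"`, `"t3"`.
#' @param condition `"cued"`, `"noncued"` or `"all"`.
#' @return proportion in [0, 1], or NA.
#' @export
retention <- function(table, from = "t2", to = "t3", condition = "all") {
  tab <- cond_rows(behavior_valid(table), condition)
  denom <- isTRUE_vec(tab[[from]])
  if (sum(denom) == 0) {
    warning("retention: empty denominator; undefined")
    return(NA_real_)
  }
  sum(denom & isTRUE_vec(tab[[to]])) / sum(denom)
}

#' TMR benefit score
#'
#' Cued minus non-cued conditional T2->T3 retention for one subject:
#' the behavioral benefit of cueing on overnight consolidation, in
#' [-1, 1]. Subjects with an undefined retention on either side yield NA.
#'
#' @param table a `nap_behavior` table for one subject.
#' @return the benefit score, or NA.
#' @export
tmr_benefit <- function(table) {
  rc <- suppressWarnings(retention(table, "t2", "t3", "cued"))
  rn <- suppressWarnings(retention(table, "t2", "t3", "noncued"))
  if (is.na(rc) || is.na(rn)) {
    warning("tmr_benefit: undefined retention; subject excluded")
    return(NA_real_)
  }
  rc - rn
}

#' Cueing-awareness discrimination index
#'
#' Hit rate (cued items identified as replayed) minus false-alarm rate
#' (non-cued items identified as replayed), per subject. Zero means
#' participants could not tell which adjectives were replayed.
#'
#' @param table a `nap_behavior` table for one subject with a
#'   `discrim_yes` column.
#' @return index in [-1, 1], or NA when a condition set is empty.
#' @export
discrimination_index <- function(table) {
  tab <- behavior_valid(table)
  cued <- cond_rows(tab, "cued"); nonc <- cond_rows(tab, "noncued")
  if (nrow(cued) == 0 || nrow(nonc) == 0) {
    warning("discrimination_index: empty condition set; undefined")
    return(NA_real_)
  }
  mean(isTRUE_vec(cued$discrim_yes)) - mean(isTRUE_vec(nonc$discrim_yes))
}

#' Cohort behavioral summary
#'
#' Applies the per-subject scores across a multi-subject table.
#'
#' @param table a `nap_behavior` table with a `subject` column.
#' @return data.frame: `subject`, `retention_t2_cued`,
#'   `retention_t2_noncued`, `retention_t3_cued`, `retention_t3_noncued`,
#'   `benefit`, `discrimination`.
#' @export
behavior_summary <- function(table) {
  do.call(rbind, lapply(split(table, table$subject), function(tab) {
    data.frame(
      subject = tab$subject[1],
      retention_t2_cued = suppressWarnings(retention(tab, "t1", "t2", "cued")),
      retention_t2_noncued = suppressWarnings(retention(tab, "t1", "t2", "noncued")),
      retention_t3_cued = suppressWarnings(retention(tab, "t2", "t3", "cued")),
      retention_t3_noncued = suppressWarnings(retention(tab, "t2", "t3", "noncued")),
      benefit = suppressWarnings(tmr_benefit(tab)),
      discrimination = suppressWarnings(discrimination_index(tab)))
  }))
}
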