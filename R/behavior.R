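# Signal-detection analysis of press logs: hit / false-alarm counts per
# condition cell, extreme-rate correction, d-prime and criterion, and
# condition-level repeated-measures inference.

#' Score presses into signal-detection counts per condition cell
#'
#' Block-initial trials (no n-back reference) are excluded; presses on such
#' trials are ignored with a warning. A hit is a press on an n-back trial;
#' a false alarm is a press on any other scoreable trial. Counts are pooled
#' over the two blocks of the same condition.
#'
#' @param plan an `experiment_plan`.
#' @param presses tibble from [simulate_responses()] (columns `block`,
#'   `trial`, `pressed`).
#' @return tibble per condition cell: `n_targets`, `n_nontargets`, `hits`,
#'   `false_alarms`.
#' @export
score_presses <- function(plan, presses) {
  tr <- dplyr::left_join(plan$trials, presses, by = c("block", "trial"))
  if (anyNA(tr$pressed)) stop("press log does not cover every trial")
  excluded <- tr$trial <= tr$memory_load
  n_ignored <- sum(tr$pressed[excluded])
  if (n_ignored > 0)
    warning(n_ignored, " press(es) on excluded block-initial trials ignored")
  tr <- tr[!excluded, ]
  dplyr::summarise(
    dplyr::group_by(tr, .data$snr_db, .data$memory_load, .data$predictability),
    n_targets = sum(.data$is_nback),
    n_nontargets = sum(!.data$is_nback),
    hits = sum(.data$pressed & .data$is_nback),
    false_alarms = sum(.data$pressed & !.data$is_nback),
    .groups = "drop"
  )
}

#' Correct extreme hit / false-alarm rates
#'
#' A rate of 0 is replaced by `1/(2n)` and a rate of 1 by `1 - 1/(2n)`,
#' where `n` is the number of trials entering the rate; other rates are
#' `count/n` unchanged.
#'
#' @param count integer count of hits or false alarms (vectorised).
#' @param n number of trials (targets or non-targets respectively).
#' @return corrected rate strictly inside (0, 1).
#' @export
correct_extreme_rate <- function(count, n) {
  if (any(n <= 0)) stop("n must be positive")
  corr <- 1 / (2 * n)
  ifelse(count == 0, corr, ifelse(count == n, 1 - corr, count / n))
}

#' Sensitivity and criterion from signal-detection counts
#'
#' Applies the extreme-rate correction, then `dprime = z(H) - z(FA)` and
#' `criterion = -(z(H) + z(FA))/2` (positive = conservative), with `z` the
#' inverse standard-normal CDF.
#'
#' @param counts tibble from [score_presses()].
#' @return the input with `hit_rate`, `fa_rate`, `dprime`, `criterion`
#'   columns appended.
#' @export
sdt_metrics <- function(counts) {
  h <- correct_extreme_rate(counts$hits, counts$n_targets)
  fa <- correct_extreme_rate(counts$false_alarms, counts$n_nontargets)
  dplyr::mutate(counts, hit_rate = h, fa_rate = fa,
                dprime = qnorm(h) - qnorm(fa),
                criterion = -(qnorm(h) + qnorm(fa)) / 2)
}

#' Repeated-measures ANOVA on a per-subject signal-detection table
#'
#' Convenience wrapper around [rm_anova()] with the three design factors
#' (SNR, memory load, distractor predictability).
#'
#' @param subject_table data frame with one row per subject x condition
#'   cell, carrying `subject`, `snr_db`, `memory_load`, `predictability`
#'   and the dependent variable.
#' @param dv dependent-variable column name (e.g. `"dprime"`,
#'   `"criterion"`, `"hit_rate"`).
#' @return ANOVA table as from [rm_anova()].
#' @export
behavior_anova <- function(subject_table, dv) {
  rm_anova(subject_table, dv,
           within = c("snr_db", "memory_load", "predictability"),
           subject = "subject")
}

#' Post-hoc criterion contrast in the easiest condition cell
#'
#' Paired t-test of criterion for predictable versus unpredictable
#' distractors within the 0 dB, 1-back cell.
#'
#' @param subject_table per-subject SDT table (see [behavior_anova()]).
#' @return list as from [paired_t()].
#' @export
criterion_posthoc <- function(subject_table) {
  cell <- subject_table[subject_table$snr_db == 0 &
                          subject_table$memory_load == 1, ]
  wide <- tidyr::pivot_wider(
    cell[, c("subject", "predictability", "criterion")],
    names_from = "predictability", values_from = "criterion")
  paired_t(wide$predictable, wide$unpredictable)
}
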