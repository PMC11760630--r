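# Shared inferential machinery: repeated-measures ANOVA with partial
# eta-squared, paired t with Cohen's d, Benjamini-Hochberg FDR and the
# t/df-based standardised partial effect size r.

#' Repeated-measures ANOVA on per-subject cell means
#'
#' Fully within-subject design with one observation per subject x cell.
#' Each effect is tested against its own subject-by-effect interaction
#' stratum. All factors here are two-level, so sphericity holds trivially
#' and no correction is applied. Partial eta-squared is
#' `F * df_num / (F * df_num + df_den)`.
#'
#' @param data data frame with one row per subject x cell.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor columns.
#' @param subject name of the subject-identifier column.
#' @return tibble with columns `effect`, `df_num`, `df_den`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
rm_anova <- function(data, dv, within, subject = "subject") {
  data <- as.data.frame(data)
  for (v in c(within, subject)) data[[v]] <- factor(data[[v]])
  cells <- table(data[c(subject, within)])
  if (any(cells != 1))
    stop("design must be balanced with one observation per subject x cell")
  rhs <- paste(within, collapse = " * ")
  form <- stats::as.formula(
    paste0("`", dv, "` ~ ", rhs, " + Error(`", subject, "`/(", rhs, "))"))
  fit <- stats::aov(form, data = data)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    keep <- terms != "Residuals"
    if (!any(keep)) next
    resid_row <- which(terms == "Residuals")
    for (i in which(keep)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        effect = terms[i],
        df_num = tab$Df[i],
        df_den = tab$Df[resid_row],
        F = tab$`F value`[i],
        p = tab$`Pr(>F)`[i]
      )
    }
  }
  out <- dplyr::bind_rows(out)
  out$partial_eta_sq <- out$F * out$df_num / (out$F * out$df_num + out$df_den)
  out
}

#' Paired-samples t-test with Cohen's d
#'
#' Two-sided test on paired differences; `cohens_d = |t| / sqrt(n)`.
#'
#' @param x,y numeric vectors of equal length (>= 2 pairs).
#' @return list with `t`, `df`, `p`, `cohens_d`, `n`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (isTRUE(all.equal(stats::var(x - y), 0)) || stats::var(x - y) == 0)
    stop("zero variance of paired differences")
  ht <- stats::t.test(x, y, paired = TRUE)
  n <- length(x)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, cohens_d = abs(unname(ht$statistic)) / sqrt(n), n = n)
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up procedure controlling the false discovery rate at level `q`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return logical vector, `TRUE` where the hypothesis is rejected.
#' @export
fdr_bh <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH") <= q
}

#' Standardised partial effect size r from a t statistic
#'
#' `r = sqrt(t^2 / (t^2 + df))`, the standardised partial effect size used
#' for mixed-effects model terms (with Satterthwaite df).
#'
#' @param t t statistic (vectorised).
#' @param df degrees of freedom (> 0).
#' @return effect size in `[0, 1)`.
#' @export
effect_size_r <- function(t, df) {
  if (any(df <= 0)) stop("df must be positive")
  sqrt(t^2 / (t^2 + df))
}
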