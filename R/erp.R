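# ERP averaging, component-window amplitude extraction and single-trial
# mixed-effects inference. Component amplitudes are mean voltages over a
# fixed time window and a small fronto-central electrode set; inference is
# by linear mixed models with a participant random intercept, Satterthwaite
# degrees of freedom and the standardised partial effect size r.

#' Canonical component windows
#'
#' P2: 160-210 ms at FC1/FCz/FC2; frontal negativity: 400-800 ms at
#' F1/Fz/F2.
#'
#' @param name `"P2"` or `"frontal_negativity"`.
#' @return list with `name`, `t_start`, `t_end`, `electrodes`.
#' @export
component_window <- function(name = c("P2", "frontal_negativity")) {
  name <- match.arg(name)
  if (name == "P2") {
    list(name = "P2", t_start = 0.160, t_end = 0.210,
         electrodes = c("FC1", "FCz", "FC2"))
  } else {
    list(name = "frontal_negativity", t_start = 0.400, t_end = 0.800,
         electrodes = c("F1", "Fz", "F2"))
  }
}

#' Average retained epochs into per-condition ERPs
#'
#' @param epochs an `epochset` (mastoid-referenced and baseline-corrected
#'   for ERP use).
#' @param by metadata columns defining the condition cells.
#' @return list with `erp` (named list of channel x sample matrices) and
#'   `cells` (tibble of condition cells with `n_trials`).
#' @export
average_erp <- function(epochs,
                        by = c("snr_db", "memory_load", "predictability")) {
  meta <- epochs$metadata[epochs$retained, , drop = FALSE]
  keep_idx <- which(epochs$retained)
  key <- interaction(meta[by], drop = TRUE, sep = "|")
  if (any(table(key) == 0)) stop("empty condition cell")
  erp <- lapply(levels(key), function(lev) {
    idx <- keep_idx[key == lev]
    apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  })
  names(erp) <- levels(key)
  cells <- dplyr::distinct(meta[by])
  cells <- cells[match(levels(key), do.call(paste, c(cells, sep = "|"))), ]
  cells$n_trials <- as.integer(table(key)[levels(key)])
  list(erp = erp, cells = cells)
}

#' Grand-average ERP over all retained trials
#'
#' @param epochs an `epochset`.
#' @return channel x sample matrix.
#' @export
grand_average <- function(epochs) {
  apply(epochs$data[epochs$retained, , , drop = FALSE], c(2, 3), mean)
}

#' Select a component window around the grand-average positive peak
#'
#' Finds the positive peak of the grand average within `search`, takes the
#' peak sample +/- `half_width` (snapped to the sample grid) as the window,
#' and the peak electrode plus its two within-row montage neighbours as the
#' electrode set.
#'
#' @param ga channel x sample grand-average matrix.
#' @param times sample times in seconds.
#' @param channels channel labels matching the rows of `ga`.
#' @param search two-element numeric search interval in seconds.
#' @param half_width half window width in seconds (default 0.025).
#' @return list with `t_start`, `t_end`, `peak_s`, `electrodes`.
#' @export
find_component_window <- function(ga, times, channels,
                                  search = c(0.1, 0.3), half_width = 0.025) {
  sel <- which(times >= search[1] & times <= search[2])
  sub <- ga[, sel, drop = FALSE]
  if (max(sub) <= 0) stop("no positive deflection in the search range")
  peak <- arrayInd(which.max(sub), dim(sub))
  peak_t <- times[sel[peak[2]]]
  step <- times[2] - times[1]
  hw <- round(half_width / step) * step
  list(t_start = peak_t - hw, t_end = peak_t + hw, peak_s = peak_t,
       electrodes = c(montage_neighbours(channels[peak[1]])[1],
                      channels[peak[1]],
                      montage_neighbours(channels[peak[1]])[2]))
}

#' Single-trial component amplitudes
#'
#' Mean voltage over the window's samples and electrodes, per retained
#' trial, joined with the trial metadata and centred effect codes
#' (`snr`, `load`, `pred`, `target`; -0.5 / +0.5).
#'
#' @param epochs an `epochset`.
#' @param window list as from [component_window()] or
#'   [find_component_window()].
#' @return tibble with one row per retained trial.
#' @export
single_trial_amplitude <- function(epochs, window) {
  sel <- epochs$times >= window$t_start - 1e-9 &
    epochs$times <= window$t_end + 1e-9
  if (!any(sel)) stop("window outside the epoch")
  idx <- channel_index(epochs, window$electrodes)
  amp <- apply(epochs$data[, idx, sel, drop = FALSE], 1, mean)
  out <- dplyr::bind_cols(epochs$metadata, effect_codes(epochs$metadata))
  out$target <- ifelse(out$is_nback, 0.5, -0.5)
  out$amplitude <- amp
  out[epochs$retained, , drop = FALSE]
}

#' Single-trial linear mixed-effects model for a component amplitude
#'
#' REML fit of `amplitude` on centred effect-coded predictors with a
#' participant random intercept; per-term t statistics, Satterthwaite df,
#' two-sided p and standardised partial effect size
#' `r = sqrt(t^2/(t^2 + df))`. Singular fits are reported via the
#' `singular` flag, never silently dropped.
#'
#' @param amplitudes tibble from [single_trial_amplitude()] (stacked over
#'   subjects, with a `subject` column).
#' @param formula model formula; the default crosses the three task
#'   factors. Alternative fixed effects (e.g. `target` for the
#'   target-vs-non-target contrast, or sub-group refits within one load
#'   level) are supported by passing a different formula / subset.
#' @return object of class `lmm_fit`: list with `terms` (tibble: term,
#'   estimate, se, t, df, p, r), `singular`, and the fitted model.
#' @export
fit_component_lmm <- function(amplitudes,
                              formula = amplitude ~ snr * load * pred +
                                (1 | subject)) {
  if (length(unique(amplitudes$subject)) < 2)
    stop("need at least 2 participants")
  fit <- lmerTest::lmer(formula, data = amplitudes, REML = TRUE)
  tab <- coef(summary(fit))
  terms <- tibble::tibble(
    term = rownames(tab),
    estimate = unname(tab[, "Estimate"]),
    se = unname(tab[, "Std. Error"]),
    t = unname(tab[, "t value"]),
    df = unname(tab[, "df"]),
    p = unname(tab[, "Pr(>|t|)"])
  )
  terms$r <- effect_size_r(terms$t, terms$df)
  structure(list(terms = terms, singular = lme4::isSingular(fit),
                 model = fit), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit>", if (x$singular) "(singular fit)" else "", "\n")
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}
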