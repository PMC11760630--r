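# Time-frequency power via moving-window FFT (Hanning taper), the
# attentional modulation index (AMI) and alpha lateralisation index (ALI),
# FDR-based time-window selection, and the window-level repeated-measures
# ANOVA.
#
# A 500-ms window has a native frequency resolution of 2 Hz; windows are
# zero-padded to `pad_to` seconds (1 s by default) so power can be
# evaluated on a 1-Hz grid. Power is computed per trial and averaged within
# attend-side / condition before any index is formed: AMI and ALI are
# ratios of averaged power, not averages of ratios.

#' Moving-window FFT power
#'
#' Hanning-tapered short-time FFT of every trial and channel, evaluated at
#' the requested window centres and frequencies. Absolute power is scaled
#' so that an on-bin sinusoid of amplitude A yields A^2. Requested centres
#' whose window would exceed the epoch are dropped (an error is raised if
#' none remain).
#'
#' @param epochs an `epochset`.
#' @param times_out window centres in seconds.
#' @param freqs frequencies in Hz; must lie on the padded FFT grid.
#' @param window moving-window length in seconds (0.5 by default).
#' @param channels optional channel subset (labels); default all.
#' @param pad_to zero-padded window length in seconds governing the
#'   frequency grid (1 s -> 1-Hz steps).
#' @return object of class `tfr_power`: list with `power` (trials x
#'   channels x freqs x times array, uV^2), axes, and the epoch metadata /
#'   retained mask.
#' @export
tfr_fft <- function(epochs, times_out = seq(-0.7, 0.7, by = 0.05),
                    freqs = 1:50, window = 0.5, channels = NULL,
                    pad_to = 1) {
  fs <- epochs$srate
  win_samp <- round(window * fs)
  nfft <- round(pad_to * fs)
  stopifnot(nfft >= win_samp)
  ch_idx <- if (is.null(channels)) seq_along(epochs$channels)
            else channel_index(epochs, channels)
  ch_lab <- epochs$channels[ch_idx]
  bins <- freqs * nfft / fs + 1
  if (any(abs(bins - round(bins)) > 1e-6))
    stop("requested frequencies do not lie on the padded FFT grid")
  bins <- round(bins)
  n_samp <- length(epochs$times)
  starts <- round((times_out - window / 2 - epochs$times[1]) * fs) + 1L
  ok <- starts >= 1L & starts + win_samp - 1L <= n_samp
  if (!any(ok)) stop("every requested window exceeds the epoch bounds")
  times_out <- times_out[ok]
  starts <- starts[ok]
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, win_samp - 1) / (win_samp - 1))
  n_tr <- dim(epochs$data)[1]
  power <- array(NA_real_,
                 c(n_tr, length(ch_idx), length(freqs), length(times_out)))
  pad <- matrix(0, nfft - win_samp, n_tr * length(ch_idx))
  for (ti in seq_along(times_out)) {
    seg <- epochs$data[, ch_idx, starts[ti]:(starts[ti] + win_samp - 1L),
                       drop = FALSE]
    m <- matrix(aperm(seg, c(3, 1, 2)), nrow = win_samp) * taper
    sp <- mvfft(rbind(m, pad))[bins, , drop = FALSE]
    amp <- 2 * abs(sp) / sum(taper)
    power[, , , ti] <- aperm(array(amp^2, c(length(bins), n_tr,
                                            length(ch_idx))), c(2, 3, 1))
  }
  structure(list(power = power, channels = ch_lab, freqs = freqs,
                 times = times_out, metadata = epochs$metadata,
                 retained = epochs$retained),
            class = "tfr_power")
}

#' @export
print.tfr_power <- function(x, ...) {
  cat(sprintf("<tfr_power> %d trials x %d channels x %d freqs x %d times\n",
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
              dim(x$power)[4]))
  invisible(x)
}

# Mean power over retained trials satisfying a metadata predicate.
mean_power <- function(tfr, keep) {
  keep <- keep & tfr$retained
  if (!any(keep)) stop("no retained trials in the requested selection")
  p <- tfr$power[keep, , , , drop = FALSE]
  arr <- apply(p, c(2, 3, 4), mean)
  array(arr, dim(tfr$power)[2:4])
}

#' Attentional modulation index
#'
#' Elementwise `(L - R) / (L + R)` of attend-left versus attend-right
#' average power; a zero denominator yields `NA`.
#'
#' @param pow_attend_left,pow_attend_right non-negative power arrays with
#'   matching dimensions.
#' @return array of the same shape in `[-1, 1]`.
#' @export
compute_ami <- function(pow_attend_left, pow_attend_right) {
  stopifnot(identical(dim(pow_attend_left), dim(pow_attend_right)),
            all(pow_attend_left >= 0, na.rm = TRUE),
            all(pow_attend_right >= 0, na.rm = TRUE))
  den <- pow_attend_left + pow_attend_right
  out <- (pow_attend_left - pow_attend_right) / den
  out[den == 0] <- NA_real_
  out
}

#' Band- and ROI-averaged AMI time series per condition level
#'
#' Averages power over trials within each attend-side (and optional
#' grouping level), forms the AMI, averages it over the alpha band, and
#' averages separately over the left and right posterior ROI electrodes.
#'
#' @param tfr a `tfr_power`.
#' @param by optional metadata column to split by (e.g.
#'   `"predictability"`); `NULL` pools all trials.
#' @param band two-element numeric frequency band in Hz (default 8-12).
#' @param roi tibble of left/right channel pairs (default
#'   [posterior_pairs()]).
#' @return tibble with columns `level`, `time`, `ami_left`, `ami_right`.
#' @export
ami_series <- function(tfr, by = NULL, band = c(8, 12),
                       roi = posterior_pairs()) {
  fsel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  li <- match(roi$left, tfr$channels)
  ri <- match(roi$right, tfr$channels)
  if (anyNA(li) || anyNA(ri)) stop("missing ROI channel in the TFR")
  levels <- if (is.null(by)) list(all = rep(TRUE, nrow(tfr$metadata)))
            else split(seq_len(nrow(tfr$metadata)), tfr$metadata[[by]]) |>
              lapply(function(i) seq_len(nrow(tfr$metadata)) %in% i)
  out <- lapply(names(levels), function(lev) {
    keep <- levels[[lev]]
    pl <- mean_power(tfr, keep & tfr$metadata$attend_side == "left")
    pr <- mean_power(tfr, keep & tfr$metadata$attend_side == "right")
    ami <- compute_ami(pl, pr)
    band_ami <- apply(ami[, fsel, , drop = FALSE], c(1, 3), mean)
    tibble::tibble(level = lev, time = tfr$times,
                   ami_left = colMeans(band_ami[li, , drop = FALSE]),
                   ami_right = colMeans(band_ami[ri, , drop = FALSE]))
  })
  dplyr::bind_rows(out)
}

#' Time-resolved alpha lateralisation index per condition cell
#'
#' Power is averaged over trials within attend-side and condition cell,
#' then over the alpha band and the posterior ROI electrodes ipsilateral
#' and contralateral to the attended side (pooling the two attend sides),
#' and finally combined as `(ipsi - contra) / (ipsi + contra)`. Positive
#' values indicate higher ipsi- than contralateral alpha power.
#'
#' @param tfr a `tfr_power`.
#' @param by metadata columns defining condition cells.
#' @param band alpha band in Hz.
#' @param roi tibble of left/right posterior pairs.
#' @return tibble with the condition columns plus `time` and `ali`.
#' @export
compute_ali <- function(tfr, by = c("snr_db", "memory_load", "predictability"),
                        band = c(8, 12), roi = posterior_pairs()) {
  fsel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  li <- match(roi$left, tfr$channels)
  ri <- match(roi$right, tfr$channels)
  if (anyNA(li) || anyNA(ri)) stop("missing ROI channel in the TFR")
  roi_band_mean <- function(p, ch) apply(p[ch, fsel, , drop = FALSE], 3, mean)
  cells <- dplyr::distinct(tfr$metadata[by])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    keep <- rep(TRUE, nrow(tfr$metadata))
    for (v in by) keep <- keep & tfr$metadata[[v]] == cells[[v]][i]
    # attend-left: ipsi = left hemisphere; attend-right: ipsi = right.
    # Cells usually hold both attend sides (pooled); single-sided input
    # (e.g. oracle fixtures) uses the one side present.
    ipsi <- contra <- 0
    n_sides <- 0L
    for (side in c("left", "right")) {
      sel <- keep & tfr$metadata$attend_side == side & tfr$retained
      if (!any(sel)) next
      p <- mean_power(tfr, sel)
      ip <- if (side == "left") li else ri
      ipsi <- ipsi + roi_band_mean(p, ip)
      contra <- contra + roi_band_mean(p, if (side == "left") ri else li)
      n_sides <- n_sides + 1L
    }
    if (n_sides == 0L) stop("no retained trials in condition cell")
    ipsi <- ipsi / n_sides
    contra <- contra / n_sides
    dplyr::bind_cols(cells[i, ],
                     tibble::tibble(time = tfr$times,
                                    ali = (ipsi - contra) / (ipsi + contra)))
  })
  dplyr::bind_rows(out)
}

#' Select significant time windows by per-time-point paired t-tests and FDR
#'
#' Paired t-tests of left- versus right-electrode AMI across subjects at
#' every time point, Benjamini-Hochberg correction across time points, and
#' contiguous significant runs returned as windows.
#'
#' @param ami_left,ami_right numeric matrices, subjects x time points.
#' @param times window-centre times in seconds.
#' @param q FDR level (0.05 by default).
#' @return list with `windows` (tibble: `t_start`, `t_end`), `mask`
#'   (logical per time point) and `p` (uncorrected p-values).
#' @export
select_windows <- function(ami_left, ami_right, times, q = 0.05) {
  stopifnot(identical(dim(ami_left), dim(ami_right)),
            ncol(ami_left) == length(times), nrow(ami_left) >= 2)
  p <- vapply(seq_along(times), function(ti) {
    stats::t.test(ami_left[, ti], ami_right[, ti], paired = TRUE)$p.value
  }, numeric(1))
  mask <- fdr_bh(p, q)
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sig <- which(runs$values)
  windows <- tibble::tibble(t_start = times[starts[sig]],
                            t_end = times[ends[sig]])
  list(windows = windows, mask = mask, p = p)
}

#' Window-mean ALI per condition cell
#'
#' @param ali tibble from [compute_ali()].
#' @param windows named list of two-element numeric windows, by default the
#'   pre-stimulus window T1 (-0.5 to -0.35 s) and post-stimulus window T2
#'   (0.3 to 0.5 s).
#' @return tibble with a `window` column and `ali` averaged over each
#'   window's time points.
#' @export
window_mean_ali <- function(ali, windows = list(T1 = c(-0.5, -0.35),
                                                T2 = c(0.3, 0.5))) {
  out <- lapply(names(windows), function(w) {
    rng <- windows[[w]]
    sub <- ali[ali$time >= rng[1] - 1e-9 & ali$time <= rng[2] + 1e-9, ]
    if (nrow(sub) == 0) stop("window ", w, " contains no time points")
    grp <- setdiff(names(sub), c("time", "ali"))
    agg <- dplyr::summarise(dplyr::group_by(sub, dplyr::across(
      dplyr::all_of(grp))), ali = mean(.data$ali), .groups = "drop")
    agg$window <- w
    agg
  })
  dplyr::bind_rows(out)
}

#' Repeated-measures ANOVA on window-mean ALI
#'
#' 2 x 2 x 2 x 2 within-subject ANOVA with factors SNR, memory load,
#' predictability and time window.
#'
#' @param ali_windows tibble with one row per subject x condition cell x
#'   window, columns `subject`, `snr_db`, `memory_load`, `predictability`,
#'   `window`, `ali`.
#' @return ANOVA table as from [rm_anova()].
#' @export
ali_window_anova <- function(ali_windows) {
  rm_anova(ali_windows, "ali",
           within = c("snr_db", "memory_load", "predictability", "window"),
           subject = "subject")
}
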