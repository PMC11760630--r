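# Deterministic epoch-level preprocessing: zero-phase band-pass filtering,
# amplitude-based trial rejection, re-referencing, baseline correction and
# exclusion of block-initial trials.

apply_channelwise <- function(epochs, fun) {
  d <- epochs$data
  dims <- dim(d)
  m <- matrix(aperm(d, c(3, 1, 2)), nrow = dims[3])  # samples x (trials*channels)
  m <- apply(m, 2, fun)
  epochs$data <- aperm(array(m, c(dims[3], dims[1], dims[2])), c(2, 3, 1))
  epochs
}

#' Zero-phase band-pass filter
#'
#' Butterworth filtering applied forward and backward (`signal::filtfilt`),
#' so no latency shift is introduced: a 2nd-order high-pass section and a
#' 6th-order low-pass section in cascade. A low-pass cutoff at or above 45%
#' of the sampling rate is clipped with a warning.
#'
#' @param epochs an `epochset`.
#' @param high_pass high-pass edge in Hz (0.1 by default).
#' @param low_pass low-pass edge in Hz (100 by default).
#' @return filtered `epochset`.
#' @export
bandpass_filter <- function(epochs, high_pass = 0.1, low_pass = 100) {
  if (!all(is.finite(epochs$data))) stop("non-finite data")
  fs <- epochs$srate
  max_lp <- 0.45 * fs
  if (low_pass >= max_lp) {
    warning(sprintf("low-pass %g Hz clipped to %g Hz (sampling rate %g Hz)",
                    low_pass, max_lp, fs))
    low_pass <- max_lp
  }
  hp <- signal::butter(2, high_pass / (fs / 2), type = "high")
  lp <- signal::butter(6, low_pass / (fs / 2), type = "low")
  # demean first: a 0.1-Hz IIR high-pass cannot settle within a 2-s epoch,
  # so the DC component is removed explicitly before zero-phase filtering
  apply_channelwise(epochs, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x - mean(x)))
  })
}

#' Flag trials whose absolute amplitude exceeds a threshold
#'
#' A trial is retained iff max |amplitude| over all channels and samples is
#' at or below `threshold` (160 microvolts by default). The mask is
#' combined (AND) with any existing mask.
#'
#' @param epochs an `epochset`.
#' @param threshold microvolts.
#' @return `epochset` with an updated `retained` mask.
#' @export
reject_amplitude <- function(epochs, threshold = 160) {
  peak <- apply(abs(epochs$data), 1, max)
  epochs$retained <- epochs$retained & (peak <= threshold)
  epochs
}

#' Re-reference epochs
#'
#' `"average"` subtracts the instantaneous mean over all channels (channel
#' mean becomes exactly zero at every sample); `"mastoids"` subtracts the
#' mean of TP9 and TP10 from every channel.
#'
#' @param epochs an `epochset`.
#' @param scheme `"average"` or `"mastoids"`.
#' @return re-referenced `epochset`.
#' @export
rereference <- function(epochs, scheme = c("average", "mastoids")) {
  scheme <- match.arg(scheme)
  d <- epochs$data
  ref <- if (scheme == "average") {
    apply(d, c(1, 3), mean)                       # trials x samples
  } else {
    idx <- channel_index(epochs, c("TP9", "TP10"))
    (d[, idx[1], ] + d[, idx[2], ]) / 2
  }
  for (ch in seq_len(dim(d)[2])) d[, ch, ] <- d[, ch, ] - ref
  epochs$data <- d
  epochs$reference <- scheme
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts the per-trial, per-channel mean over the baseline window, so
#' the baseline mean becomes exactly zero.
#'
#' @param epochs an `epochset`.
#' @param window two-element numeric, baseline window in seconds
#'   (default -0.2 to 0).
#' @return baseline-corrected `epochset`.
#' @export
baseline_correct <- function(epochs, window = c(-0.2, 0)) {
  sel <- epochs$times >= window[1] - 1e-9 & epochs$times <= window[2] + 1e-9
  if (!any(sel)) stop("baseline window contains no samples")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over samples
  epochs
}

#' Drop block-initial trials that have no n-back reference
#'
#' Removes trial 1 in 1-back blocks and trials 1-2 in 2-back blocks, for an
#' `epochset` or a trial table carrying `trial` and `memory_load` columns.
#'
#' @param x an `epochset` or a data frame of trials.
#' @return the filtered object.
#' @export
drop_block_initial_trials <- function(x) {
  if (inherits(x, "epochset")) {
    keep <- x$metadata$trial > x$metadata$memory_load
    epochs_subset(x, keep)
  } else {
    x[x$trial > x$memory_load, , drop = FALSE]
  }
}

#' Detect flat or extreme-variance channels and repair by neighbour averaging
#'
#' Deterministic stand-in for visual bad-channel screening: a channel is
#' flagged when its pooled standard deviation is below `flat_tol` or more
#' than `var_factor` times the median channel standard deviation. Flagged
#' channels are replaced by the mean of their within-row montage
#' neighbours.
#'
#' @param epochs an `epochset`.
#' @param flat_tol microvolts; channels quieter than this are flat.
#' @param var_factor multiple of the median channel SD above which a
#'   channel is extreme.
#' @return `epochset` with repaired channels and an attribute
#'   `repaired_channels`.
#' @export
repair_bad_channels <- function(epochs, flat_tol = 1e-6, var_factor = 5) {
  sds <- apply(epochs$data, 2, sd)
  bad <- which(sds < flat_tol | sds > var_factor * stats::median(sds))
  for (ch in bad) {
    nb <- tryCatch(montage_neighbours(epochs$channels[ch]),
                   error = function(e) NULL)
    nb <- nb[nb %in% epochs$channels]
    if (length(nb) == 0) next
    idx <- channel_index(epochs, nb)
    epochs$data[, ch, ] <- apply(epochs$data[, idx, , drop = FALSE],
                                 c(1, 3), mean)
  }
  attr(epochs, "repaired_channels") <- epochs$channels[bad]
  epochs
}
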