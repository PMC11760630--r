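# In-memory container for epoched EEG: trials x channels x samples plus
# axes and per-trial metadata.

#' Construct an epoch set
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param times numeric vector of sample times in seconds (uniform grid).
#' @param channels character vector of channel labels.
#' @param srate sampling rate in Hz.
#' @param metadata tibble with one row per trial (condition fields etc.).
#' @param retained logical vector, one per trial; trials flagged `FALSE`
#'   are excluded from averages and statistics downstream.
#' @param reference reference state: "none", "average" or "mastoids".
#' @return object of class `epochset`.
#' @export
new_epochset <- function(data, times, channels, srate, metadata,
                         retained = rep(TRUE, dim(data)[1]),
                         reference = "none") {
  stopifnot(length(dim(data)) == 3,
            dim(data)[2] == length(channels),
            dim(data)[3] == length(times),
            nrow(metadata) == dim(data)[1],
            length(retained) == dim(data)[1])
  dt <- diff(times)
  stopifnot(all(abs(dt - 1 / srate) < 1e-9))
  structure(list(data = data, times = times, channels = channels,
                 srate = srate, metadata = tibble::as_tibble(metadata),
                 retained = retained, reference = reference),
            class = "epochset")
}

#' @export
print.epochset <- function(x, ...) {
  cat(sprintf("<epochset> %d trials x %d channels x %d samples @ %g Hz (%.3g..%.3g s), ref=%s, %d retained\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$srate,
              min(x$times), max(x$times), x$reference, sum(x$retained)))
  invisible(x)
}

#' Subset an epoch set by trial index
#'
#' Metadata and the retained mask follow the trials.
#'
#' @param epochs an `epochset`.
#' @param idx integer or logical trial index.
#' @return a new `epochset`.
#' @export
epochs_subset <- function(epochs, idx) {
  new_epochset(epochs$data[idx, , , drop = FALSE], epochs$times,
               epochs$channels, epochs$srate, epochs$metadata[idx, ],
               epochs$retained[idx], epochs$reference)
}

channel_index <- function(epochs, labels) {
  i <- match(labels, epochs$channels)
  if (anyNA(i)) stop("missing channel(s): ",
                     paste(labels[is.na(i)], collapse = ", "))
  i
}
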