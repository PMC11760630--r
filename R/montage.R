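# 64-channel 10-10 montage with schematic 2D coordinates.
#
# x runs left (-1) to right (+1), y posterior (-1) to anterior (+1). The
# coordinates are a schematic flat projection: sufficient for hemisphere
# assignment, within-row neighbour lookup and Gaussian spatial weighting of
# simulated components; no volume conduction is modelled.

montage_row <- function(labels, y, x) {
  tibble::tibble(channel = labels, x = x, y = y)
}

#' Electrode montage used throughout the package
#'
#' @return tibble with columns `channel`, `x`, `y`, `hemisphere`
#'   (left/right/midline) and `row` (anterior-posterior row index used for
#'   neighbour lookup).
#' @export
predistract_montage <- function() {
  rows <- list(
    montage_row(c("Fp1", "Fp2"), 0.95, c(-0.2, 0.2)),
    montage_row(c("AF7", "AF3", "AF4", "AF8"), 0.80,
                c(-0.85, -0.4, 0.4, 0.85)),
    montage_row(c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"), 0.60,
                c(-0.85, -0.65, -0.4, -0.15, 0, 0.15, 0.4, 0.65, 0.85)),
    montage_row(c("FT9", "FT7", "FC5", "FC3", "FC1", "FCz",
                  "FC2", "FC4", "FC6", "FT8", "FT10"), 0.30,
                c(-1, -0.85, -0.65, -0.4, -0.15, 0, 0.15, 0.4, 0.65, 0.85, 1)),
    montage_row(c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"), 0.00,
                c(-0.85, -0.65, -0.4, -0.15, 0, 0.15, 0.4, 0.65, 0.85)),
    montage_row(c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz",
                  "CP2", "CP4", "CP6", "TP8", "TP10"), -0.30,
                c(-1, -0.85, -0.65, -0.4, -0.15, 0, 0.15, 0.4, 0.65, 0.85, 1)),
    montage_row(c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"), -0.60,
                c(-0.85, -0.65, -0.4, -0.15, 0, 0.15, 0.4, 0.65, 0.85)),
    montage_row(c("PO9", "PO7", "PO3", "PO4", "PO8", "PO10"), -0.80,
                c(-1, -0.85, -0.4, 0.4, 0.85, 1)),
    montage_row(c("O1", "Oz", "O2"), -0.95, c(-0.3, 0, 0.3))
  )
  out <- dplyr::bind_rows(rows, .id = "row")
  out$row <- as.integer(out$row)
  out$hemisphere <- ifelse(out$x < 0, "left", ifelse(out$x > 0, "right", "midline"))
  out[, c("channel", "x", "y", "hemisphere", "row")]
}

#' Posterior electrode pairs used for alpha-lateralisation indices
#'
#' The 12 left/right posterior pairs over parieto-occipital scalp.
#'
#' @return tibble with columns `left` and `right`.
#' @export
posterior_pairs <- function() {
  tibble::tibble(
    left  = c("TP9", "TP7", "CP5", "CP3", "CP1", "P7",
              "P5", "P3", "P1", "PO7", "PO3", "O1"),
    right = c("TP10", "TP8", "CP6", "CP4", "CP2", "P8",
              "P6", "P4", "P2", "PO8", "PO4", "O2")
  )
}

# Left and right within-row neighbours of a channel (by schematic x).
montage_neighbours <- function(channel, montage = predistract_montage()) {
  i <- match(channel, montage$channel)
  if (is.na(i)) stop("unknown channel: ", channel)
  row <- montage[montage$row == montage$row[i], ]
  row <- row[order(row$x), ]
  j <- match(channel, row$channel)
  if (j == 1L || j == nrow(row))
    stop("channel ", channel, " has no neighbour on both sides")
  c(row$channel[j - 1L], row$channel[j + 1L])
}
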