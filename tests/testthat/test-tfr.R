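sinusoid_epochs <- function(amps, freq = 10, srate = 100, channels = NULL,
                            phase = 0, metadata = NULL) {
  t <- seq(-1, 1 - 1 / srate, by = 1 / srate)
  n_ch <- length(amps)
  x <- array(0, c(1, n_ch, length(t)))
  for (c in seq_len(n_ch))
    x[1, c, ] <- amps[c] * sin(2 * pi * freq * t + phase)
  make_epochs(x, srate = srate, channels = channels, metadata = metadata)
}

test_that("moving-window power peaks at the oscillation frequency and scales quadratically", {
  ep <- sinusoid_epochs(2)
  tfr <- tfr_fft(ep, times_out = seq(-0.5, 0.5, 0.25), freqs = 1:40)
  pw <- tfr$power[1, 1, , ]
  expect_true(all(apply(pw, 2, which.max) == 10))
  # on-bin amplitude-squared calibration and time stability
  expect_equal(unname(pw[10, ]), rep(4, 5), tolerance = 1e-2)
  tfr2 <- tfr_fft(sinusoid_epochs(4), times_out = 0, freqs = 10)
  expect_equal(tfr2$power[1, 1, 1, 1] / tfr$power[1, 1, 10, 3], 4,
               tolerance = 1e-6)
})

test_that("white-noise power is flat across frequencies within Monte-Carlo error", {
  set.seed(16)
  x <- array(rnorm(60 * 1 * 200), c(60, 1, 200))
  tfr <- tfr_fft(make_epochs(x, srate = 100), times_out = 0, freqs = 5:45)
  avg <- apply(tfr$power[, 1, , 1], 2, mean)
  expect_lt(max(avg) / min(avg), 2.2)
  expect_lt(abs(lm(avg ~ seq_along(avg))$coef[2]), 0.01 * mean(avg))
})

test_that("edge windows are dropped and off-grid frequencies rejected", {
  ep <- sinusoid_epochs(1)
  tfr <- tfr_fft(ep, times_out = c(-0.9, 0, 0.9), freqs = 10)
  expect_equal(tfr$times, 0)
  expect_error(tfr_fft(ep, times_out = c(-2, 2), freqs = 10), "bounds")
  expect_error(tfr_fft(ep, times_out = 0, freqs = 10.3), "grid")
})

test_that("AMI follows its ratio definition and is antisymmetric", {
  l <- array(c(1, 2, 0, 1), c(2, 2, 1))
  r <- array(c(1, 2, 3, 0), c(2, 2, 1))
  ami <- compute_ami(l, r)
  expect_equal(ami[1, 1, 1], 0)       # L = R
  expect_equal(ami[2, 2, 1], 1)       # R = 0
  expect_equal(ami[1, 2, 1], -1)      # L = 0
  expect_equal(compute_ami(array(1, c(1, 1, 1)), array(3, c(1, 1, 1)))[1],
               -0.5)                  # L=1, R=3
  expect_equal(compute_ami(r, l), -ami)
  zero <- array(0, c(1, 1, 1))
  expect_true(is.na(compute_ami(zero, zero)[1]))
  expect_true(all(abs(ami[!is.na(ami)]) <= 1))
})

test_that("pipeline ALI equals the closed-form gain ratio for a noise-free oscillator", {
  g_ipsi <- 1.3
  g_contra <- 0.7
  meta <- tibble::tibble(trial = 1, memory_load = 1, attend_side = "left",
                         snr_db = 0, predictability = "predictable")
  ep <- sinusoid_epochs(c(g_ipsi, g_contra), channels = c("P3", "P4"),
                        metadata = meta)
  roi <- tibble::tibble(left = "P3", right = "P4")
  tfr <- tfr_fft(ep, times_out = c(-0.4, 0.4), freqs = 8:12)
  ali <- compute_ali(tfr, roi = roi)
  expected <- (g_ipsi^2 - g_contra^2) / (g_ipsi^2 + g_contra^2)
  expect_equal(ali$ali, rep(expected, 2), tolerance = 1e-6)
  # attend-right with mirrored gains gives the identical ALI
  meta_r <- dplyr::mutate(meta, attend_side = "right")
  ep_r <- sinusoid_epochs(c(g_contra, g_ipsi), channels = c("P3", "P4"),
                          metadata = meta_r)
  ali_r <- compute_ali(tfr_fft(ep_r, times_out = c(-0.4, 0.4), freqs = 8:12),
                       roi = roi)
  expect_equal(ali_r$ali, ali$ali, tolerance = 1e-9)
  # swapping ipsi/contra flips the sign exactly
  ep_s <- sinusoid_epochs(c(g_contra, g_ipsi), channels = c("P3", "P4"),
                          metadata = meta)
  ali_s <- compute_ali(tfr_fft(ep_s, times_out = c(-0.4, 0.4), freqs = 8:12),
                       roi = roi)
  expect_equal(ali_s$ali, -ali$ali, tolerance = 1e-9)
})

test_that("ALI = 1/3 when ipsilateral power doubles contralateral power", {
  # direct arithmetic on the definition via mirrored two-trial input
  meta <- tibble::tibble(trial = 1:2, memory_load = 1,
                         attend_side = c("left", "right"), snr_db = 0,
                         predictability = "predictable")
  t <- seq(-1, 1 - 0.01, by = 0.01)
  x <- array(0, c(2, 2, length(t)))
  x[1, 1, ] <- sqrt(2) * sin(2 * pi * 10 * t)  # attend L: ipsi = left
  x[1, 2, ] <- 1 * sin(2 * pi * 10 * t)
  x[2, 1, ] <- 1 * sin(2 * pi * 10 * t)        # attend R: ipsi = right
  x[2, 2, ] <- sqrt(2) * sin(2 * pi * 10 * t)
  ep <- make_epochs(x, srate = 100, channels = c("P3", "P4"), metadata = meta)
  ali <- compute_ali(tfr_fft(ep, times_out = 0, freqs = 8:12),
                     roi = tibble::tibble(left = "P3", right = "P4"))
  expect_equal(ali$ali, 1 / 3, tolerance = 1e-6)
})

test_that("window selection returns nothing for p = 1 and brackets a strong effect", {
  times <- seq(-0.7, 0.7, 0.05)
  set.seed(17)
  n <- 15
  null_l <- matrix(rnorm(n * length(times)), n)
  sel0 <- select_windows(null_l, matrix(rnorm(n * length(times)), n), times)
  expect_equal(nrow(sel0$windows), 0)  # null lateralisation
  # strong lateralisation confined to 0.3-0.5 s
  eff <- matrix(0, n, length(times))
  eff[, times >= 0.3 - 1e-9 & times <= 0.5 + 1e-9] <- 2.5
  sel <- select_windows(null_l + eff, matrix(rnorm(n * length(times)), n),
                        times)
  expect_gte(nrow(sel$windows), 1)
  expect_true(any(sel$windows$t_start <= 0.3 + 1e-9 &
                    sel$windows$t_end >= 0.5 - 1e-9))
})

test_that("window-mean ALI and the 2x2x2x2 ANOVA wire together", {
  set.seed(18)
  n <- 10
  cells <- tidyr::expand_grid(subject = 1:n, snr_db = c(0, -10),
                              memory_load = 1:2,
                              predictability = c("predictable",
                                                 "unpredictable"),
                              window = c("T1", "T2"))
  cells$ali <- rnorm(nrow(cells), 0.05) + 1.0 * (cells$window == "T2")
  an <- ali_window_anova(cells)
  expect_equal(nrow(an), 15)  # 4 mains, 6 two-way, 4 three-way, 1 four-way
  expect_gt(an$F[an$effect == "window"], 10)
  expect_true(all(an$partial_eta_sq >= 0 & an$partial_eta_sq < 1))
  # a factor with no effect and no structure stays small on average
  expect_lt(median(an$F[an$effect != "window"]), 5)
})
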