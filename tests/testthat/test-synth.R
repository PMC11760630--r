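# Generator tests: response model, noise spectrum, alpha placement and
# ground-truth reporting. A quiet parameter set (no noise, no jitter, no
# evoked activity) exposes the deterministic structure.

quiet_eeg_params <- function(srate = 100, channels = NULL) {
  p <- default_eeg_params(srate)
  p$noise_sd <- 0
  p$alpha_jitter_sdlog <- 1e-9
  p$ali_subject_sd <- 0
  p$erp_subject_sd <- 0
  p$erp_components$amp_base[] <- 0
  p$erp_components$amp_snr[] <- 0
  p$erp_components$amp_load[] <- 0
  p$erp_components$amp_pred[] <- 0
  p$erp_components$amp_load_pred[] <- 0
  if (!is.null(channels)) p$channels <- channels
  p
}

test_that("press probabilities follow the SDT generative model", {
  plan <- build_experiment(21)
  # symmetric null: d'=0, c=0 presses half the time on targets and non-targets
  null <- default_behavior_params()
  null$dprime <- 0
  null$criterion <- 0
  pr <- simulate_responses(plan, null, seed = 1)
  tr <- dplyr::left_join(plan$trials, pr, by = c("block", "trial"))
  expect_lt(abs(mean(tr$pressed) - 0.5), 3 * sqrt(0.25 / nrow(tr)))

  # d'=2.123, c=0.22 gives hit rate ~0.8 and false-alarm rate ~0.1
  pars <- default_behavior_params()
  pars$dprime <- 2.123
  pars$criterion <- 0.22
  hits <- fas <- 0; nt <- nn <- 0
  for (s in 1:20) {
    pr <- simulate_responses(plan, pars, seed = 100 + s)
    tr <- dplyr::left_join(plan$trials, pr, by = c("block", "trial"))
    hits <- hits + sum(tr$pressed & tr$is_nback)
    fas <- fas + sum(tr$pressed & !tr$is_nback)
    nt <- nt + sum(tr$is_nback); nn <- nn + sum(!tr$is_nback)
  }
  expect_lt(abs(hits / nt - 0.8), 0.02)
  expect_lt(abs(fas / nn - 0.1), 0.01)

  # extreme criterion: nobody presses; reaction times only when pressed
  pars$criterion <- 50
  pr <- simulate_responses(plan, pars, seed = 2)
  expect_false(any(pr$pressed))
  expect_true(all(is.na(pr$rt_s)))
})

test_that("reaction times lie in the 2-s response window", {
  plan <- build_experiment(22, n_trials = 40)
  pr <- simulate_responses(plan, seed = 5)
  expect_true(all(pr$rt_s[pr$pressed] > 0 & pr$rt_s[pr$pressed] <= 2))
  expect_true(all(is.na(pr$rt_s[!pr$pressed])))
})

test_that("background noise has a ~1/f power spectrum", {
  plan <- build_experiment(23, n_trials = 6)
  pars <- default_eeg_params(250)
  pars$alpha_amp <- 0
  pars$erp_components$amp_base[] <- 0
  pars$erp_components[, c("amp_snr", "amp_load", "amp_pred",
                          "amp_load_pred")] <- 0
  ep <- simulate_eeg_epochs(plan, pars, seed = 8)
  x <- ep$data[1:40, 1:10, ]
  n <- dim(x)[3]
  f <- (seq_len(n) - 1) * ep$srate / n
  sel <- f >= 2 & f <= 40
  pw <- 0
  for (tr in 1:40) for (ch in 1:10)
    pw <- pw + abs(fft(x[tr, ch, ]))^2 / (40 * 10)
  slope <- coef(lm(log(pw[sel]) ~ log(f[sel])))[2]
  expect_lt(abs(slope - (-1)), 0.15)
})

test_that("alpha power concentrates in the 8-12 Hz band at posterior channels only", {
  plan <- build_experiment(24, n_trials = 6)
  pars <- quiet_eeg_params(250)
  ep <- simulate_eeg_epochs(plan, pars, seed = 9)
  band_power <- function(ch) {
    i <- match(ch, ep$channels)
    x <- ep$data[1, i, ]
    p <- abs(fft(x))^2
    f <- (seq_along(x) - 1) * ep$srate / length(x)
    c(band = sum(p[f >= 8 & f <= 12]), rest = sum(p[f > 14 & f <= 45]))
  }
  post <- band_power("PO3")
  expect_gt(post["band"], 1000 * max(post["rest"], 1e-12))
  front <- band_power("FCz")
  expect_lt(front["band"], 1e-9)
})

test_that("zero lateralisation gives equal left/right posterior power in expectation", {
  plan <- build_experiment(25, n_trials = 8)
  pars <- quiet_eeg_params(100)
  pars$ali_windows$ali <- 0
  pars$noise_sd <- 1
  ep <- simulate_eeg_epochs(plan, pars, seed = 10)
  roi <- posterior_pairs()
  li <- match(roi$left, ep$channels); ri <- match(roi$right, ep$channels)
  pl <- mean(ep$data[, li, ]^2)
  prt <- mean(ep$data[, ri, ]^2)
  expect_lt(abs(pl - prt) / (pl + prt), 0.02)
})

test_that("erp amplitude zero leaves post-stimulus condition averages flat", {
  plan <- build_experiment(26, n_trials = 6)
  pars <- quiet_eeg_params(100)
  pars$alpha_amp <- 0
  ep <- simulate_eeg_epochs(plan, pars, seed = 11)
  expect_equal(max(abs(ep$data[, match("FCz", ep$channels), ])), 0)
})

test_that("injected evoked components appear with configured amplitude at the centre electrode", {
  plan <- build_experiment(27, n_trials = 6)
  pars <- quiet_eeg_params(250)
  pars$alpha_amp <- 0
  pars$erp_components$amp_base <- c(0, 0, 2.5, 0)
  ep <- simulate_eeg_epochs(plan, pars, seed = 12)
  fcz <- ep$data[1, match("FCz", ep$channels), ]
  expect_equal(max(fcz), 2.5, tolerance = 1e-2)  # peak lies between samples
  expect_equal(ep$times[which.max(fcz)], 0.184, tolerance = 0.01)
})

test_that("ground-truth report round-trips every injected parameter", {
  bp <- default_behavior_params()
  epars <- default_eeg_params()
  gt <- ground_truth_report(bp, epars)
  expect_identical(gt$behavior, bp)
  expect_identical(gt$ali, epars$ali_windows)
  expect_equal(gt$erp$amp_base, epars$erp_components$amp_base)
  expect_equal(gt$erp$amp_load_pred, epars$erp_components$amp_load_pred)
})

test_that("epoch simulation is seed-deterministic and carries aligned metadata", {
  plan <- build_experiment(28, n_trials = 4)
  pars <- quiet_eeg_params(100)
  e1 <- simulate_eeg_epochs(plan, pars, seed = 3)
  e2 <- simulate_eeg_epochs(plan, pars, seed = 3)
  expect_identical(e1$data, e2$data)
  expect_identical(e1$metadata, plan$trials)
  bad <- pars
  bad$ali_windows$ali[1] <- 1
  expect_error(simulate_eeg_epochs(plan, bad), "magnitude")
})
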