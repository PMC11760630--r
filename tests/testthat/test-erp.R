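# A 200-Hz grid puts the 185-ms grand-average peak and the 160/210-ms
# window edges exactly on samples.

erp_test_params <- function(p2_amp = 2.5, pred_effect = 0, srate = 200) {
  p <- default_eeg_params(srate)
  p$channels <- c("F1", "Fz", "F2", "FC1", "FCz", "FC2", "TP9", "TP10")
  p$alpha_amp <- 0
  p$ali_subject_sd <- 0
  p$erp_subject_sd <- 0
  p$noise_sd <- 0
  p$erp_components$amp_base <- c(0, 0, p2_amp, 0)
  p$erp_components[, c("amp_snr", "amp_load", "amp_pred",
                       "amp_load_pred")] <- 0
  p$erp_components$amp_pred[3] <- pred_effect
  p
}

test_that("condition averages equal the constituent epochs where those are identical", {
  x <- array(rep(1:4, each = 2 * 50), c(4, 2, 50)) # two identical per pair
  meta <- tibble::tibble(trial = 1:4, memory_load = 1,
                         cond = c("a", "a", "b", "b"))
  x[2, , ] <- x[1, , ]; x[4, , ] <- x[3, , ]
  ep <- make_epochs(x, metadata = meta)
  avg <- average_erp(ep, by = "cond")
  expect_equal(avg$erp[["a"]], x[1, , ])
  expect_equal(avg$erp[["b"]], x[3, , ])
  expect_equal(avg$cells$n_trials, c(2L, 2L))
  # zero-mean noise averages towards zero
  set.seed(15)
  y <- array(rnorm(400 * 1 * 20), c(400, 1, 20))
  epn <- make_epochs(y, metadata = tibble::tibble(trial = 1:400,
                                                  memory_load = 1, cond = "a"))
  expect_lt(max(abs(average_erp(epn, "cond")$erp[["a"]])), 4 / sqrt(400))
  expect_error(average_erp(ep, by = "trial"), NA)
})

test_that("window selection finds the 185-ms peak and returns 160-210 ms at FC1/FCz/FC2", {
  plan <- build_experiment(51, n_trials = 8)
  ep <- simulate_eeg_epochs(plan, erp_test_params(), seed = 20)
  ga <- grand_average(ep)
  w <- find_component_window(ga, ep$times, ep$channels)
  expect_equal(w$peak_s, 0.185)
  expect_equal(w$t_start, 0.160)
  expect_equal(w$t_end, 0.210)
  expect_equal(w$electrodes, c("FC1", "FCz", "FC2"))
  # a peak moved to 200 ms gives 175-225 ms by definition
  p <- erp_test_params(); p$erp_components$peak_s[3] <- 0.2
  ep2 <- simulate_eeg_epochs(plan, p, seed = 21)
  w2 <- find_component_window(grand_average(ep2), ep2$times, ep2$channels)
  expect_equal(c(w2$t_start, w2$t_end), c(0.175, 0.225))
  # flat waveform: error
  flat <- make_epochs(array(0, c(2, 3, 400)), srate = 200,
                      channels = c("FC1", "FCz", "FC2"))
  expect_error(find_component_window(grand_average(flat), flat$times,
                                     flat$channels), "positive")
})

test_that("single-trial amplitudes are window means and linear in the injected gain", {
  const <- make_epochs(array(3.5, c(2, 3, 400)), srate = 200,
                       channels = c("FC1", "FCz", "FC2"),
                       metadata = tibble::tibble(
                         trial = 1:2, memory_load = 1, snr_db = 0,
                         predictability = "predictable", is_nback = FALSE))
  amp <- single_trial_amplitude(const, component_window("P2"))
  expect_equal(amp$amplitude, c(3.5, 3.5))

  plan <- build_experiment(52, n_trials = 8)
  a1 <- single_trial_amplitude(
    simulate_eeg_epochs(plan, erp_test_params(2.5), seed = 22),
    component_window("P2"))
  a2 <- single_trial_amplitude(
    simulate_eeg_epochs(plan, erp_test_params(5.0), seed = 22),
    component_window("P2"))
  expect_equal(a2$amplitude, 2 * a1$amplitude, tolerance = 1e-9)

  # electrode-set mean equals a manual mean over the same channels/samples
  ep <- simulate_eeg_epochs(plan, erp_test_params(), seed = 23)
  w <- component_window("P2")
  manual <- apply(ep$data[, match(w$electrodes, ep$channels),
                          ep$times >= w$t_start - 1e-9 &
                            ep$times <= w$t_end + 1e-9], 1, mean)
  expect_equal(single_trial_amplitude(ep, w)$amplitude, manual)
  expect_error(single_trial_amplitude(ep, list(t_start = 5, t_end = 6,
                                               electrodes = "FCz")),
               "outside")
})

test_that("the single-trial LMM with negligible subject variance matches OLS", {
  plan <- build_experiment(53, n_trials = 8)
  p <- erp_test_params(pred_effect = 0.8)
  p$noise_sd <- 4
  amps <- dplyr::bind_rows(lapply(1:2, function(s) {
    a <- single_trial_amplitude(simulate_eeg_epochs(plan, p, seed = 30 + s),
                                component_window("P2"))
    a$subject <- s
    a
  }))
  fit <- fit_component_lmm(amps)
  ols <- lm(amplitude ~ snr * load * pred, data = amps)
  expect_equal(fit$terms$estimate, unname(coef(ols)), tolerance = 1e-3)
  expect_true(is.logical(fit$singular))
  # Eq-3 consistency: every r equals sqrt(t^2/(t^2+df)) to 4 decimals
  expect_equal(round(fit$terms$r, 4),
               round(sqrt(fit$terms$t^2 / (fit$terms$t^2 + fit$terms$df)), 4))
  expect_error(fit_component_lmm(amps[amps$subject == 1, ]), "participants")
})

test_that("the LMM supports the target-vs-non-target contrast", {
  plan <- build_experiment(54, n_trials = 20)
  p <- erp_test_params()
  p$noise_sd <- 2
  amps <- dplyr::bind_rows(lapply(1:3, function(s) {
    ep <- simulate_eeg_epochs(plan, p, seed = 40 + s)
    # deterministic target effect injected directly on the amplitudes
    a <- single_trial_amplitude(ep, component_window("P2"))
    a$amplitude <- a$amplitude - 1.2 * a$target
    a$subject <- s
    a
  }))
  fit <- fit_component_lmm(amps, amplitude ~ target + (1 | subject))
  est <- fit$terms[fit$terms$term == "target", ]
  expect_lt(est$estimate, 0)
  expect_lt(est$p, 0.001)
})
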