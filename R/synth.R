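# Synthetic behaviour and EEG with known ground truth. The generator
# emulates the statistical structure the analysis assumes: per-condition
# signal-detection behaviour; 1/f background EEG; hemisphere-lateralised
# ~10-Hz alpha whose lateralisation index varies by condition and time
# window; and condition-dependent evoked components (P1, N1, P2, frontal
# negativity) with Gaussian spatial profiles on the montage.

#' Default generative signal-detection parameters
#'
#' One row per SNR x memory-load x predictability cell. Sensitivity drops
#' and the criterion grows more conservative under 2-back load; the easiest
#' cell (0 dB, 1-back, predictable distractors) carries a less conservative
#' criterion, the behavioural predictability effect the analysis should
#' recover.
#'
#' @return tibble with columns `snr_db`, `memory_load`, `predictability`,
#'   `dprime`, `criterion`.
#' @export
default_behavior_params <- function() {
  cells <- condition_grid()
  cells$dprime <- ifelse(cells$memory_load == 1, 3.0, 2.0)
  cells$criterion <- 0.35 + 0.30 * (cells$memory_load == 2) -
    0.17 * (cells$snr_db == 0 & cells$memory_load == 1 &
              cells$predictability == "predictable")
  cells
}

#' Default generative EEG parameters
#'
#' @param sampling_rate Hz; 250 by default so a 2-s epoch holds 500 samples.
#' @param n_trials_hint unused placeholder kept for config completeness.
#' @return list of generator settings: montage channels, alpha oscillation
#'   settings with per-window lateralisation targets, evoked component
#'   table, and 1/f noise settings.
#' @export
default_eeg_params <- function(sampling_rate = 250, n_trials_hint = NULL) {
  list(
    sampling_rate = sampling_rate,
    channels = predistract_montage()$channel,
    alpha_freq = 10,                 # Hz
    alpha_amp = 8,                   # uV sinusoid amplitude at ROI channels;
                                     # posterior alpha dominates the 1/f
                                     # background in the 8-12 Hz band
    alpha_jitter_sdlog = 0.2,        # log-normal trial-to-trial amplitude jitter
    # Lateralisation targets per analysis window and predictability level.
    # T1 precedes stimulus onset; T2 follows it.
    ali_windows = tibble::tibble(
      window = c("T1", "T1", "T2", "T2"),
      t_start = c(-0.5, -0.5, 0.3, 0.3),
      t_end = c(-0.35, -0.35, 0.5, 0.5),
      predictability = c("predictable", "unpredictable",
                         "predictable", "unpredictable"),
      ali = c(0, -0.1, 0.2, 0.2)
    ),
    ali_subject_sd = 0.05,           # between-subject jitter of the targets
    # Gain plateaus extend past each window by half the spectral-estimation
    # window so moving-window power centred anywhere inside the nominal
    # window sees the full plateau (window-mean ALI equals the target).
    ali_plateau_extend = 0.25,       # s
    ali_ramp = 0.05,                 # s, raised-cosine ramp length
    erp_components = tibble::tibble(
      component = c("P1", "N1", "P2", "frontal_negativity"),
      type = c("gaussian", "gaussian", "gaussian", "plateau"),
      t_start = c(NA, NA, NA, 0.4),
      t_end = c(NA, NA, NA, 0.8),
      peak_s = c(0.05, 0.10, 0.185, NA),
      width_s = c(0.02, 0.03, 0.025, 0.05),
      channel = c("FCz", "FCz", "FCz", "Fz"),
      spatial_sd = 0.35,
      amp_base = c(1.5, -3.0, 2.5, -2.0),
      amp_snr = c(0, 0, 0.6, -0.4),       # effect of 0 dB vs -10 dB
      amp_load = c(0, 0, 0.25, 0.5),      # effect of 2-back vs 1-back
      amp_pred = c(0, 0, 0.4, 0.1),       # effect of unpredictable vs predictable
      amp_load_pred = c(0, 0, 0, -0.6)    # load x predictability interaction
    ),
    erp_subject_sd = 1.0,            # uV, per-subject component offset
    noise_exponent = 1,              # 1/f slope of background EEG
    noise_sd = 8                     # uV broadband noise per channel
  )
}

#' Simulate button presses from known signal-detection parameters
#'
#' Per condition cell, presses follow the equal-variance Gaussian model:
#' `P(press | n-back) = pnorm(dprime/2 - criterion)` and
#' `P(press | non-target) = pnorm(-dprime/2 - criterion)`. Reaction times
#' are uniform in (0, 2] when a press occurs.
#'
#' @param plan an `experiment_plan`.
#' @param params tibble as from [default_behavior_params()].
#' @param seed optional integer seed.
#' @return tibble with columns `block`, `trial`, `pressed`, `rt_s`.
#' @export
simulate_responses <- function(plan, params = default_behavior_params(),
                               seed = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  tr <- dplyr::left_join(plan$trials, params,
                         by = c("snr_db", "memory_load", "predictability"))
  if (anyNA(tr$dprime)) stop("params must cover every condition cell")
  with_seed_maybe(seed, {
    p_press <- ifelse(tr$is_nback,
                      pnorm(tr$dprime / 2 - tr$criterion),
                      pnorm(-tr$dprime / 2 - tr$criterion))
    pressed <- runif(nrow(tr)) < p_press
    # 2 - U[0, 2) lies in (0, 2]: presses always fall inside the window
    rt <- ifelse(pressed, 2 - runif(nrow(tr), 0, 2), NA_real_)
    tibble::tibble(block = tr$block, trial = tr$trial,
                   pressed = pressed, rt_s = rt)
  })
}

# 1/f noise: white Gaussian noise shaped in the frequency domain by
# |f|^(-exponent/2), globally rescaled so the expected sd is sd_target.
noise_1f <- function(n_samp, k, srate, exponent, sd_target) {
  freqs <- c(0, seq_len(n_samp - 1)) * srate / n_samp
  freqs <- pmin(freqs, srate - freqs)   # two-sided spectrum
  scale <- c(0, freqs[-1]^(-exponent / 2))
  out <- matrix(0, n_samp, k)
  chunk <- max(1L, floor(2e7 / n_samp))
  for (start in seq(1L, k, by = chunk)) {
    idx <- start:min(k, start + chunk - 1L)
    w <- matrix(rnorm(n_samp * length(idx)), n_samp)
    f <- mvfft(w) * scale
    out[, idx] <- Re(mvfft(f, inverse = TRUE)) / n_samp
  }
  out * sd_target / sqrt(mean(scale^2))
}

# Time course of the target lateralisation index: plateaus (extended past
# each nominal window) with raised-cosine ramps to zero between them.
ali_profile <- function(times, windows, extend, ramp) {
  a <- numeric(length(times))
  for (i in seq_len(nrow(windows))) {
    lo <- windows$t_start[i] - extend
    hi <- windows$t_end[i] + extend
    w <- numeric(length(times))
    w[times >= lo & times <= hi] <- 1
    left <- times >= lo - ramp & times < lo
    w[left] <- 0.5 * (1 + cos(pi * (lo - times[left]) / ramp))
    right <- times > hi & times <= hi + ramp
    w[right] <- 0.5 * (1 + cos(pi * (times[right] - hi) / ramp))
    a <- a + windows$ali[i] * w
  }
  pmax(pmin(a, 0.95), -0.95)
}

erp_kernel <- function(times, comp) {
  if (comp$type == "gaussian") {
    exp(-(times - comp$peak_s)^2 / (2 * comp$width_s^2)) * (times > 0)
  } else {
    k <- numeric(length(times))
    k[times >= comp$t_start & times <= comp$t_end] <- 1
    ramp <- comp$width_s
    left <- times >= comp$t_start - ramp & times < comp$t_start
    k[left] <- 0.5 * (1 + cos(pi * (comp$t_start - times[left]) / ramp))
    right <- times > comp$t_end & times <= comp$t_end + ramp
    k[right] <- 0.5 * (1 + cos(pi * (times[right] - comp$t_end) / ramp))
    k
  }
}

# Effect codes (-0.5 / +0.5): 0 dB, 2-back, unpredictable are the +0.5 level.
effect_codes <- function(metadata) {
  tibble::tibble(
    snr = ifelse(metadata$snr_db == 0, 0.5, -0.5),
    load = ifelse(metadata$memory_load == 2, 0.5, -0.5),
    pred = ifelse(metadata$predictability == "unpredictable", 0.5, -0.5)
  )
}

#' Simulate epoched EEG for one subject
#'
#' Each epoch (-1 to 1 s, time-locked to the target/distractor pair onset)
#' is the sum of 1/f background noise on every channel, a ~10-Hz alpha
#' oscillation at the posterior ROI channels whose hemispheric amplitude
#' gains `sqrt(1 + a(t))` (ipsilateral) and `sqrt(1 - a(t))`
#' (contralateral) realise the configured lateralisation-index time course
#' `a(t)`, and post-stimulus evoked components with condition-dependent
#' amplitudes and Gaussian scalp profiles. Alpha phase is random per trial
#' and channel.
#'
#' @param plan an `experiment_plan`.
#' @param params list as from [default_eeg_params()].
#' @param seed optional integer seed (one subject per call; subject-level
#'   offsets are drawn inside).
#' @return an `epochset` with the plan's trial table as metadata.
#' @export
simulate_eeg_epochs <- function(plan, params = default_eeg_params(),
                                seed = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (any(abs(params$ali_windows$ali) >= 1))
    stop("lateralisation targets must have magnitude < 1")
  with_seed_maybe(seed, {
    fs <- params$sampling_rate
    times <- seq(-1, 1 - 1 / fs, by = 1 / fs)
    n_samp <- length(times)
    channels <- params$channels
    montage <- predistract_montage()
    montage <- montage[match(channels, montage$channel), ]
    if (anyNA(montage$channel)) stop("unknown channel in params$channels")
    meta <- plan$trials
    n_tr <- nrow(meta)
    n_ch <- length(channels)

    # background 1/f noise
    noise <- noise_1f(n_samp, n_tr * n_ch, fs, params$noise_exponent,
                      params$noise_sd)
    data <- aperm(array(noise, c(n_samp, n_tr, n_ch)), c(2, 3, 1))

    # lateralised alpha at posterior ROI channels
    pairs <- posterior_pairs()
    roi <- c(pairs$left, pairs$right)
    roi <- roi[roi %in% channels]
    roi_idx <- match(roi, channels)
    hemi <- montage$hemisphere[roi_idx]
    subj_ali_shift <- rnorm(1, 0, params$ali_subject_sd)
    profiles <- lapply(c("predictable", "unpredictable"), function(p) {
      w <- params$ali_windows[params$ali_windows$predictability == p, ]
      w$ali <- pmax(pmin(w$ali + subj_ali_shift, 0.95), -0.95)
      ali_profile(times, w, params$ali_plateau_extend, params$ali_ramp)
    })
    names(profiles) <- c("predictable", "unpredictable")
    omega <- 2 * pi * params$alpha_freq * times
    sdl <- params$alpha_jitter_sdlog
    n_roi <- length(roi_idx)
    # vectorised over trials sharing a predictability x attend-side profile
    grp <- split(seq_len(n_tr),
                 paste(meta$predictability, meta$attend_side))
    for (g in grp) {
      a <- profiles[[meta$predictability[g[1]]]]
      ipsi <- hemi == meta$attend_side[g[1]]
      gain <- outer(rep(1, n_roi), sqrt(1 - a))
      gain[ipsi, ] <- rep(sqrt(1 + a), each = sum(ipsi))
      k <- length(g)
      amps <- params$alpha_amp * rlnorm(k, -sdl^2 / 2, sdl)
      phases <- matrix(runif(k * n_roi, 0, 2 * pi), k, n_roi)
      sig <- array(sin(outer(as.vector(phases), omega, "+")),
                   c(k, n_roi, n_samp)) * amps
      sig <- sig * aperm(array(gain, c(n_roi, n_samp, k)), c(3, 1, 2))
      data[g, roi_idx, ] <- data[g, roi_idx, ] + sig
    }

    # evoked components
    codes <- effect_codes(meta)
    comps <- params$erp_components
    full_montage <- predistract_montage()
    for (i in seq_len(nrow(comps))) {
      comp <- comps[i, ]
      centre <- full_montage[full_montage$channel == comp$channel, ]
      if (nrow(centre) != 1) stop("unknown component centre: ", comp$channel)
      w_ch <- exp(-((montage$x - centre$x)^2 + (montage$y - centre$y)^2) /
                    (2 * comp$spatial_sd^2))
      k <- erp_kernel(times, comp)
      amp <- comp$amp_base + rnorm(1, 0, params$erp_subject_sd) +
        codes$snr * comp$amp_snr + codes$load * comp$amp_load +
        codes$pred * comp$amp_pred +
        codes$load * codes$pred * comp$amp_load_pred
      data <- data + outer(outer(amp, w_ch), k)
    }

    new_epochset(data, times, channels, fs, meta, reference = "none")
  })
}

#' Report every injected ground-truth effect
#'
#' Echoes the generative parameters in tidy form so recovery tests and
#' pipeline reports can place estimates next to their targets.
#'
#' @param behavior_params tibble as from [default_behavior_params()].
#' @param eeg_params list as from [default_eeg_params()].
#' @return list of tibbles: `behavior`, `ali`, `erp`.
#' @export
ground_truth_report <- function(behavior_params = default_behavior_params(),
                                eeg_params = default_eeg_params()) {
  erp <- eeg_params$erp_components
  list(
    behavior = behavior_params,
    ali = eeg_params$ali_windows,
    erp = erp[, c("component", "amp_base", "amp_snr", "amp_load",
                  "amp_pred", "amp_load_pred")]
  )
}
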