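# End-to-end seeded pipeline: design -> synthetic data -> preprocessing ->
# behaviour / ERP / alpha-lateralisation analyses -> recovery report.

#' Pipeline configuration
#'
#' Collects every analysis constant with the study's value as default:
#' 33 subjects, 120 pairs per block, 0.1-100 Hz band-pass, 160 uV rejection
#' threshold, -0.2-0 s baseline, P2 160-210 ms at FC1/FCz/FC2, frontal
#' negativity 400-800 ms at F1/Fz/F2, 8-12 Hz alpha band over the posterior
#' ROI, T1 -0.5 to -0.35 s and T2 0.3-0.5 s, FDR level 0.05. `n_trials`
#' and `n_subjects` may be reduced for desk-scale runs.
#'
#' @param seed integer master seed.
#' @param n_subjects number of simulated participants (study value 33).
#' @param n_trials pairs per block (study value 120).
#' @param sampling_rate EEG sampling rate in Hz (generator default 250; all
#'   analysis windows are in seconds, so results are rate-invariant).
#' @param out_dir optional output directory for TSV/JSON artefacts.
#' @param bandpass two-element numeric filter band in Hz, or `NULL` to skip
#'   filtering.
#' @param behavior_params,eeg_params generator parameter overrides.
#' @param tfr_times moving-window centres for the time-frequency stage.
#' @param alpha_band,ali_windows,reject_threshold,baseline,q_fdr analysis
#'   constants (see description).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 33, n_trials = 120,
                            sampling_rate = 250, out_dir = NULL,
                            bandpass = c(0.1, 100),
                            behavior_params = default_behavior_params(),
                            eeg_params = default_eeg_params(sampling_rate),
                            tfr_times = seq(-0.7, 0.7, by = 0.05),
                            alpha_band = c(8, 12),
                            ali_windows = list(T1 = c(-0.5, -0.35),
                                               T2 = c(0.3, 0.5)),
                            reject_threshold = 160,
                            baseline = c(-0.2, 0),
                            q_fdr = 0.05) {
  structure(list(seed = seed, n_subjects = n_subjects, n_trials = n_trials,
                 sampling_rate = sampling_rate, out_dir = out_dir,
                 bandpass = bandpass, behavior_params = behavior_params,
                 eeg_params = eeg_params, tfr_times = tfr_times,
                 alpha_band = alpha_band, ali_windows = ali_windows,
                 reject_threshold = reject_threshold, baseline = baseline,
                 q_fdr = q_fdr),
            class = "pipeline_config")
}

# One subject: simulate, preprocess, and extract stage-level tables.
analyze_subject <- function(subject, seeds, config) {
  plan <- build_experiment(seeds[1], n_trials = config$n_trials)
  presses <- simulate_responses(plan, config$behavior_params, seeds[2])
  sdt <- suppressWarnings(score_presses(plan, presses)) |> sdt_metrics()
  sdt$subject <- subject

  epochs <- simulate_eeg_epochs(plan, config$eeg_params, seeds[3])
  if (!is.null(config$bandpass))
    epochs <- bandpass_filter(epochs, config$bandpass[1], config$bandpass[2])
  epochs <- reject_amplitude(epochs, config$reject_threshold)
  epochs <- drop_block_initial_trials(epochs)

  # ERP branch: mastoid reference, baseline correction, single-trial
  # amplitudes in the canonical component windows
  erp_epochs <- baseline_correct(rereference(epochs, "mastoids"),
                                 config$baseline)
  amp <- lapply(c("P2", "frontal_negativity"), function(comp) {
    a <- single_trial_amplitude(erp_epochs, component_window(comp))
    a$component <- comp
    a$subject <- subject
    a
  })
  ga <- grand_average(erp_epochs)

  # alpha branch: average reference, ROI-restricted moving-window power
  tfr_epochs <- rereference(epochs, "average")
  roi <- posterior_pairs()
  tfr <- tfr_fft(tfr_epochs, times_out = config$tfr_times,
                 freqs = seq(config$alpha_band[1], config$alpha_band[2]),
                 channels = c(roi$left, roi$right))
  ali <- compute_ali(tfr, band = config$alpha_band, roi = roi)
  ali$subject <- subject
  ali_win <- window_mean_ali(ali, config$ali_windows)
  ali_win$subject <- subject
  ami <- ami_series(tfr, by = "predictability", band = config$alpha_band,
                    roi = roi)
  ami$subject <- subject

  list(sdt = sdt, amplitudes = dplyr::bind_rows(amp), grand_average = ga,
       ali = ali, ali_windows = ali_win, ami = ami)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Deterministic given the config seed: per-subject sub-seeds are derived
#' with [make_subseeds()], so subjects can be processed in any order with
#' identical results. Produces the behavioural signal-detection tables and
#' ANOVAs, the single-trial P2 / frontal-negativity mixed models (including
#' the per-load-level frontal-negativity refits and the exploratory
#' target-vs-non-target P2 contrast), the AMI-based window selection, the
#' window-level ALI ANOVA, and a recovery table placing every injected
#' ground-truth effect next to its estimate.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results (invisibly also written to
#'   `config$out_dir` as TSV/JSON when set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- matrix(make_subseeds(config$seed, config$n_subjects * 3L),
                  ncol = 3L)
  per_subject <- lapply(seq_len(config$n_subjects), function(s) {
    analyze_subject(s, seeds[s, ], config)
  })

  sdt <- dplyr::bind_rows(lapply(per_subject, `[[`, "sdt"))
  behavior <- list(
    sdt = sdt,
    anova_dprime = behavior_anova(sdt, "dprime"),
    anova_criterion = behavior_anova(sdt, "criterion"),
    anova_hit_rate = behavior_anova(sdt, "hit_rate"),
    criterion_posthoc = criterion_posthoc(sdt)
  )

  amps <- dplyr::bind_rows(lapply(per_subject, `[[`, "amplitudes"))
  p2 <- amps[amps$component == "P2", ]
  fn <- amps[amps$component == "frontal_negativity", ]
  erp <- list(
    p2_lmm = fit_component_lmm(p2),
    fn_lmm = fit_component_lmm(fn),
    fn_lmm_load1 = fit_component_lmm(fn[fn$memory_load == 1, ],
                                     amplitude ~ snr * pred + (1 | subject)),
    fn_lmm_load2 = fit_component_lmm(fn[fn$memory_load == 2, ],
                                     amplitude ~ snr * pred + (1 | subject)),
    p2_target_lmm = fit_component_lmm(p2, amplitude ~ target + (1 | subject))
  )
  ga <- Reduce(`+`, lapply(per_subject, `[[`, "grand_average")) /
    config$n_subjects
  times <- seq(-1, 1 - 1 / config$sampling_rate, by = 1 / config$sampling_rate)
  erp$p2_window <- find_component_window(ga, times,
                                         config$eeg_params$channels)

  ali_win <- dplyr::bind_rows(lapply(per_subject, `[[`, "ali_windows"))
  ami <- dplyr::bind_rows(lapply(per_subject, `[[`, "ami"))
  selection <- lapply(split(ami, ami$level), function(a) {
    a <- a[order(a$subject, a$time), ]
    n_t <- length(unique(a$time))
    select_windows(matrix(a$ami_left, ncol = n_t, byrow = TRUE),
                   matrix(a$ami_right, ncol = n_t, byrow = TRUE),
                   sort(unique(a$time)), config$q_fdr)
  })
  alpha <- list(
    ali = dplyr::bind_rows(lapply(per_subject, `[[`, "ali")),
    ali_windows = ali_win,
    window_selection = selection,
    anova = ali_window_anova(ali_win),
    anova_T1 = rm_anova(ali_win[ali_win$window == "T1", ], "ali",
                        c("snr_db", "memory_load", "predictability")),
    anova_T2 = rm_anova(ali_win[ali_win$window == "T2", ], "ali",
                        c("snr_db", "memory_load", "predictability"))
  )

  truth <- ground_truth_report(config$behavior_params, config$eeg_params)
  recovery <- recovery_table(truth, sdt, ali_win, erp)

  result <- list(config = config, behavior = behavior, erp = erp,
                 alpha = alpha, ground_truth = truth, recovery = recovery)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

# Injected effects next to their recovered estimates.
recovery_table <- function(truth, sdt, ali_win, erp) {
  beh_est <- dplyr::summarise(
    dplyr::group_by(sdt, .data$snr_db, .data$memory_load, .data$predictability),
    dprime_est = mean(.data$dprime), criterion_est = mean(.data$criterion),
    .groups = "drop")
  beh <- dplyr::left_join(truth$behavior, beh_est,
                          by = c("snr_db", "memory_load", "predictability"))
  ali_est <- dplyr::summarise(
    dplyr::group_by(ali_win, .data$window, .data$predictability),
    ali_est = mean(.data$ali), .groups = "drop")
  ali <- dplyr::left_join(truth$ali, ali_est,
                          by = c("window", "predictability"))
  p2_terms <- erp$p2_lmm$terms
  fn_terms <- erp$fn_lmm$terms
  erp_tab <- tibble::tibble(
    component = c("P2", "P2", "P2", "frontal_negativity",
                  "frontal_negativity", "frontal_negativity"),
    term = c("snr", "load", "pred", "snr", "load", "load:pred"),
    injected = c(truth$erp$amp_snr[truth$erp$component == "P2"],
                 truth$erp$amp_load[truth$erp$component == "P2"],
                 truth$erp$amp_pred[truth$erp$component == "P2"],
                 truth$erp$amp_snr[truth$erp$component == "frontal_negativity"],
                 truth$erp$amp_load[truth$erp$component == "frontal_negativity"],
                 truth$erp$amp_load_pred[
                   truth$erp$component == "frontal_negativity"]),
    estimate = c(p2_terms$estimate[match(c("snr", "load", "pred"),
                                         p2_terms$term)],
                 fn_terms$estimate[match(c("snr", "load", "load:pred"),
                                         fn_terms$term)])
  )
  list(behavior = beh, ali = ali, erp = erp_tab)
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) utils::write.table(
    x, file.path(dir, name), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(result$behavior$sdt, "sdt_by_subject.tsv")
  wt(result$behavior$anova_dprime, "anova_dprime.tsv")
  wt(result$behavior$anova_criterion, "anova_criterion.tsv")
  wt(result$behavior$anova_hit_rate, "anova_hit_rate.tsv")
  wt(result$alpha$ali_windows, "ali_windows.tsv")
  wt(result$alpha$anova, "anova_ali.tsv")
  wt(result$erp$p2_lmm$terms, "lmm_p2.tsv")
  wt(result$erp$fn_lmm$terms, "lmm_frontal_negativity.tsv")
  summary <- list(
    seed = result$config$seed,
    n_subjects = result$config$n_subjects,
    criterion_posthoc = result$behavior$criterion_posthoc,
    p2_window = result$erp$p2_window,
    window_selection = lapply(result$alpha$window_selection,
                              function(s) s$windows),
    recovery = result$recovery
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
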