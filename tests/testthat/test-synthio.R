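# Synthetic session generator: timing, determinism, calibration, coupling.

test_that("trial tables satisfy ordering, range and consistency invariants", {
  for (sd in 1:4) {
    cfg <- sim_config(n_trials = 50, seed = sd)
    tr <- generate_trials(cfg)$trials
    expect_true(all(tr$iti_start_s < tr$quiescent_start_s))
    expect_true(all(tr$quiescent_start_s < tr$quiescent_end_s))
    expect_true(all(tr$quiescent_end_s <= tr$stim_onset_s))
    expect_true(all(tr$stim_onset_s < tr$gocue_s))
    q <- tr$quiescent_end_s - tr$quiescent_start_s
    expect_true(all(q >= 0.5 & q <= 2))
    g <- tr$gocue_s - tr$stim_onset_s
    expect_true(all(g >= 0.3 & g <= 0.8))
    has_resp <- !is.na(tr$response_s)
    expect_true(all(tr$response_s[has_resp] > tr$gocue_s[has_resp]))
    expect_true(all(tr$response_s[has_resp] <= tr$response_window_end_s[has_resp]))
    # Correct Reject / False Alarm appear only on zero-contrast trials
    zero <- tr$contrast_left == 0 & tr$contrast_right == 0
    expect_true(all(tr$outcome[!zero] %in%
                      c("CorrectChoice", "IncorrectChoice", "Miss")))
    expect_true(all(tr$outcome[zero] %in% c("CorrectReject", "FalseAlarm")))
    expect_equal(tr$rewarded,
                 tr$outcome %in% c("CorrectChoice", "CorrectReject"))
    # classification from raw events reproduces the generated outcomes
    re <- classify_trials(tr[, setdiff(names(tr), "outcome")])
    expect_equal(re$outcome, tr$outcome)
  }
})

test_that("identical seeds give bit-identical sessions; different seeds differ", {
  cfg <- sim_config(n_trials = 12, grid_size = 8, seed = 7)
  a <- suppressWarnings(generate_session(cfg))
  b <- suppressWarnings(generate_session(cfg))
  expect_identical(a$movie$calcium_frames, b$movie$calcium_frames)
  expect_identical(a$movie$hemo_frames, b$movie$hemo_frames)
  expect_identical(a$trials, b$trials)
  expect_identical(a$spikes$spike_times_s, b$spikes$spike_times_s)
  expect_identical(a$pupil$diameter, b$pupil$diameter)
  d <- suppressWarnings(generate_session(sim_config(n_trials = 12, grid_size = 8,
                                                    seed = 8)))
  expect_false(identical(a$trials$stim_onset_s, d$trials$stim_onset_s))
})

test_that("latent state holds its configured lag-1 autocorrelation", {
  cfg <- sim_config(n_trials = 4000, state_ar_coeff = 0.7, seed = 9)
  s <- generate_trials(cfg)$trial_state
  expect_lt(abs(cor(s[-1], s[-length(s)]) - 0.7), 0.05)
  expect_lt(abs(mean(s)), 0.1)
})

test_that("quiescent-range guards: rejection and downstream-exclusion warning", {
  expect_error(generate_session(sim_config(quiescent_range_s = c(0.3, 0.6))),
               "0.7")
  expect_warning(generate_session(sim_config(n_trials = 4, grid_size = 4,
                                             quiescent_range_s = c(0.5, 2),
                                             seed = 1),
                                  include_spikes = FALSE,
                                  include_pupil = FALSE),
                 "excluded")
})

test_that("null configuration yields indistinguishable Choice/Miss power", {
  cfg <- sim_config(n_trials = 150, band_power_effect_db = 0,
                    outcome_logit_slope = 0, quiescent_range_s = c(0.8, 2),
                    seed = 12)
  s <- generate_session(cfg, include_spikes = FALSE, include_pupil = FALSE)
  cal <- compress_movie(s$movie$calcium_frames, s$movie$timestamps_cal, k = 40)
  tab <- band_power_table(cal, s$trials, default_roi_set(16))
  ch <- tab$outcome %in% c("CorrectChoice", "IncorrectChoice")
  mi <- tab$outcome == "Miss"
  pv <- wilcox.test(tab$db_VIS[ch], tab$db_VIS[mi])$p.value
  expect_gt(pv, 0.005)
  expect_lt(abs(mean(tab$db_VIS[ch]) - mean(tab$db_VIS[mi])), 1)
})

test_that("amplitude doubling on half the trials raises their band power by ~6.02 dB", {
  # outcome-conditioned fallback: slope 0 with a -6.0206 dB target doubles
  # the amplitude on Miss trials; verified with the pixel-space periodogram
  # oracle, not the package's spectral path
  cfg <- sim_config(n_trials = 150, band_power_effect_db = -20 * log10(2),
                    outcome_logit_slope = 0, quiescent_range_s = c(0.8, 2),
                    miss_base_rate = 0.5, noise_sd = 0.01, seed = 13)
  s <- generate_session(cfg, include_spikes = FALSE, include_pupil = FALSE)
  qw <- extract_quiescent_windows(s$trials)
  px <- 5 * 16 + 5 + 1
  tr_px <- s$movie$calcium_frames[px, ]
  p <- vapply(seq_len(nrow(qw)), function(i) {
    sel <- s$movie$timestamps_cal >= qw$start_s[i] &
      s$movie$timestamps_cal < qw$end_s[i]
    oracle_band_power(matrix(tr_px[sel], 1), 35, c(3, 6))
  }, numeric(1))
  out <- s$trials$outcome[qw$trial]
  mi <- out == "Miss"; ch <- out %in% c("CorrectChoice", "IncorrectChoice")
  dd <- mean(10 * log10(p[mi])) - mean(10 * log10(p[ch]))
  expect_lt(abs(dd - 6.0206), 0.8)
})

test_that("noise-free single-mode movies have the stated exact rank", {
  base <- list(n_trials = 6, grid_size = 6, noise_sd = 0, baseline_level = 0,
               contrast_levels = 0, quiescent_range_s = c(0.8, 2), seed = 14)
  cfg1 <- do.call(sim_config, c(base, hemo_gain_map_scale = 0))
  s1 <- generate_session(cfg1, include_spikes = FALSE, include_pupil = FALSE)
  sv1 <- svd(s1$movie$calcium_frames)$d
  expect_equal(sum(sv1 > sv1[1] * 1e-8), 1L)     # rank 1: single state mode

  cfg2 <- do.call(sim_config, c(base, hemo_gain_map_scale = 1))
  s2 <- generate_session(cfg2, include_spikes = FALSE, include_pupil = FALSE)
  sv2 <- svd(s2$movie$calcium_frames)$d
  expect_equal(sum(sv2 > sv2[1] * 1e-8), 2L)     # plus rank-1 artifact

  # hemo_gain_map_scale = 0: calcium channel has no heartbeat-band power
  # above the (zero) noise floor
  hb <- oracle_band_power(s1$movie$calcium_frames, 35, c(9, 13))
  bb <- oracle_band_power(s1$movie$calcium_frames, 35, c(0.5, 17.49))
  expect_lt(max(hb / bb), 0.01)
})

test_that("spike coupling controls fluorescence-MUA coherence", {
  # zero coupling: coherence sits at the estimator bias floor
  s0 <- suppressWarnings(generate_session(
    sim_config(n_trials = 30, spike_coupling_gain = 0, seed = 15),
    include_pupil = FALSE))
  cal0 <- compress_movie(s0$movie$calcium_frames, s0$movie$timestamps_cal, k = 30)
  mua0 <- bin_and_smooth_mua(s0$spikes, 35, t_range = range(s0$movie$timestamps_cal))
  tr0 <- extract_pixel_trace(cal0, 4, 4)$trace
  n0 <- min(length(mua0$rate), length(tr0))
  coh0 <- coherence_spectrum(mua0$rate[1:n0], tr0[1:n0], segment_s = 4, fs = 35)
  expect_lt(mean(coh0$coherence), 4 / coh0$n_segments + 0.05)
  expect_equal(s0$spikes$clusters$type[s0$spikes$clusters$tuning > 0][1], "tuned")

  # strong coupling, low noise, large population: high coherence in the
  # 3-6 Hz signal band, collapsing above 8 Hz
  s1 <- suppressWarnings(generate_session(
    sim_config(n_trials = 100, spike_coupling_gain = 1, noise_sd = 0.03,
               n_units = 120, seed = 16), include_pupil = FALSE))
  cal1 <- compress_movie(s1$movie$calcium_frames, s1$movie$timestamps_cal, k = 40)
  mua1 <- bin_and_smooth_mua(s1$spikes, 35, t_range = range(s1$movie$timestamps_cal))
  tr1 <- extract_pixel_trace(cal1, 4, 4)$trace
  n1 <- min(length(mua1$rate), length(tr1))
  coh1 <- coherence_spectrum(mua1$rate[1:n1], tr1[1:n1], segment_s = 4, fs = 35)
  band <- coh1$freqs_hz >= 3 & coh1$freqs_hz <= 6
  expect_gt(mean(coh1$coherence[band]), 0.8)
  expect_lt(mean(coh1$coherence[coh1$freqs_hz > 8.5]),
            mean(coh1$coherence[band]) / 3)
})

test_that("logistic regression on the true state recovers the outcome slope sign", {
  hits <- 0L
  for (sd in 1:10) {
    cfg <- sim_config(n_trials = 200, seed = sd)
    tr <- generate_trials(cfg)
    stim <- tr$trials$contrast_left > 0 | tr$trials$contrast_right > 0
    y <- tr$trials$outcome[stim] == "Miss"
    fit <- glm(y ~ s, data = data.frame(y = y, s = tr$trial_state[stim]),
               family = binomial)
    if (coef(fit)[2] > 0) hits <- hits + 1L
  }
  expect_gte(hits, 10L * 0.95)
})

test_that("pupil tracks the latent state at the configured correlation", {
  s <- small_session()
  st <- s$truth$latent_state
  expect_lt(abs(cor(s$pupil$diameter, st) - 0.6), 0.15)
  # derivative is the discrete difference of diameter over time
  dt <- diff(s$pupil$timestamps_s)
  expect_equal(s$pupil$derivative[-1], diff(s$pupil$diameter) / dt,
               tolerance = 1e-12)
})

test_that("movie channels are interleaved with half-frame offsets", {
  s <- small_session()
  m <- s$movie
  expect_equal(nrow(m$calcium_frames), nrow(m$hemo_frames))
  expect_true(all(diff(m$timestamps_cal) > 0))
  off <- m$timestamps_hemo[1:100] - m$timestamps_cal[1:100]
  expect_true(all(abs(off - 1 / (2 * m$fs)) < 1e-9))
})

test_that("configs and ROI sets round-trip through YAML; spike errors guard", {
  cfg <- sim_config(n_trials = 17, band_power_effect_db = -2.25, seed = 99)
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  expect_equal(read_sim_config(f), cfg)
  rois <- default_roi_set(16)
  f2 <- tempfile(fileext = ".yaml")
  write_roi_set(rois, f2)
  expect_equal(unclass(read_roi_set(f2)), lapply(rois, as.integer),
               ignore_attr = TRUE)
  s <- small_session()
  expect_error(generate_spike_data(s$truth, s$movie,
                                   sim_config(spike_coupling_gain = -1),
                                   s$trials),
               ">= 0")
})
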