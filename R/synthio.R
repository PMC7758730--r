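# Synthetic session generator.
#
# Emulates the statistical structure the analysis assumes: dual-channel
# widefield movies at 35 Hz per channel with alternate-frame illumination, a
# trial table with enforced quiescent periods, a latent synchronization
# state that modulates 3-6 Hz power and outcome probabilities, a
# heartbeat-band hemodynamic artifact with per-pixel gain, spiking coupled
# to fluorescence below ~8 Hz plus contrast-tuned transient units, LFP and
# pupil traces. Ground truth is returned for parameter-recovery tests.

#' Configuration of a synthetic session
#'
#' Defaults encode the task's stated world: 35 Hz per illumination channel,
#' quiescent periods uniform on 0.5-2 s at the end of a 1-5 s pre-trial
#' baseline, go cue 0.3-0.8 s after stimulus onset, a 1.5-5 s response
#' window, contrasts {0, 25, 50, 100}%.
#'
#' @param grid_size pixels per side of the square imaging grid.
#' @param fs_channel frames/s per illumination channel (default 35).
#' @param n_trials number of trials.
#' @param quiescent_range_s (min, max) of the uniform quiescent duration.
#' @param gocue_delay_range_s (min, max) go-cue delay after stimulus onset.
#' @param response_window_s (min, max) of the response window duration (one
#'   duration per session is drawn from this range).
#' @param contrast_levels attainable stimulus contrasts, fractions in [0, 1].
#' @param state_ar_coeff lag-1 autocorrelation of the latent synchronization
#'   state across trials (marginally standard normal).
#' @param band_power_effect_db target Choice - Miss difference in quiescent
#'   3-6 Hz power, in dB (negative: Miss trials more synchronized).
#' @param outcome_logit_slope effect of the latent state on the log-odds of
#'   a Miss (and, negated, of a False Alarm).
#' @param hemo_gain_map_scale magnitude of the per-pixel hemodynamic artifact
#'   gain (0 disables the artifact).
#' @param heartbeat_hz center of the heartbeat artifact band (default 11;
#'   the artifact is narrowband noise within +-1 Hz).
#' @param spike_coupling_gain gain from (standardized, <8 Hz low-passed)
#'   fluorescence to population firing rate.
#' @param pupil_state_corr target correlation between pupil diameter and the
#'   latent state.
#' @param noise_sd white measurement noise SD per pixel per frame.
#' @param miss_base_rate Miss probability at latent state 0.
#' @param baseline_level constant baseline fluorescence added to the calcium
#'   channel.
#' @param n_units number of spiking units (about a third are contrast-tuned
#'   transient units; the rest follow the fluorescence-coupled rate).
#' @param light_artifact_amp amplitude of the light-pulse artifact added to
#'   the LFP at every illumination onset (0 disables).
#' @param seed integer root seed; fully determines all outputs.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(grid_size = 16L, fs_channel = 35, n_trials = 200L,
                       quiescent_range_s = c(0.5, 2),
                       gocue_delay_range_s = c(0.3, 0.8),
                       response_window_s = c(1.5, 5),
                       contrast_levels = c(0, 0.25, 0.5, 1),
                       state_ar_coeff = 0.7,
                       band_power_effect_db = -1.5,
                       outcome_logit_slope = 1,
                       hemo_gain_map_scale = 1,
                       heartbeat_hz = 11,
                       spike_coupling_gain = 1,
                       pupil_state_corr = 0.6,
                       noise_sd = 0.1,
                       miss_base_rate = 0.2,
                       baseline_level = 1,
                       n_units = 24L,
                       light_artifact_amp = 0,
                       seed = 1L) {
  for (r in list(quiescent_range_s, gocue_delay_range_s, response_window_s)) {
    stop_if(length(r) != 2L || r[1] > r[2] || any(r < 0),
            "ranges must be nonnegative (min, max) pairs with min <= max")
  }
  stop_if(fs_channel <= 12, "fs_channel must exceed 12 Hz (2 x 6 Hz band edge)")
  stop_if(any(contrast_levels < 0 | contrast_levels > 1),
          "contrast levels must be fractions in [0, 1]")
  stop_if(abs(state_ar_coeff) >= 1, "state_ar_coeff must lie in (-1, 1)")
  stop_if(heartbeat_hz + 1 > fs_channel / 2,
          "heartbeat band exceeds the channel Nyquist frequency")
  structure(list(grid_size = as.integer(grid_size), fs_channel = fs_channel,
                 n_trials = as.integer(n_trials),
                 quiescent_range_s = quiescent_range_s,
                 gocue_delay_range_s = gocue_delay_range_s,
                 response_window_s = response_window_s,
                 contrast_levels = contrast_levels,
                 state_ar_coeff = state_ar_coeff,
                 band_power_effect_db = band_power_effect_db,
                 outcome_logit_slope = outcome_logit_slope,
                 hemo_gain_map_scale = hemo_gain_map_scale,
                 heartbeat_hz = heartbeat_hz,
                 spike_coupling_gain = spike_coupling_gain,
                 pupil_state_corr = pupil_state_corr,
                 noise_sd = noise_sd, miss_base_rate = miss_base_rate,
                 baseline_level = baseline_level, n_units = as.integer(n_units),
                 light_artifact_amp = light_artifact_amp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default ROI set for a synthetic grid
#'
#' Named 0-based (row, col) pixel coordinates in the layout of the synthetic
#' spatial modes: VIS at the stimulus-response bump, the others spread over
#' the grid.
#'
#' @param grid_size pixels per side.
#' @return named list of (row, col) integer pairs (class \code{roi_set}).
#' @export
default_roi_set <- function(grid_size = 16L) {
  g <- as.integer(grid_size)
  q <- max(1L, g %/% 4L)
  rois <- list(VIS = c(q, q), SS = c(q, 3L * q), AUD = c(3L * q, q),
               RSP = c(3L * q, 3L * q), MO = c(2L * q, 2L * q))
  structure(rois, class = "roi_set")
}

# E[s | Choice] - E[s | Miss] for s ~ N(0,1), P(Miss|s) = plogis(b0 + beta s).
# Used to calibrate the state -> dB gain so the realized Choice - Miss power
# difference equals band_power_effect_db in expectation.
#' @noRd
state_gap_choice_miss <- function(b0, beta) {
  s <- seq(-6, 6, by = 0.005)
  w <- stats::dnorm(s)
  pm <- stats::plogis(b0 + beta * s)
  p_miss <- sum(w * pm); p_choice <- sum(w * (1 - pm))
  sum(s * w * (1 - pm)) / p_choice - sum(s * w * pm) / p_miss
}

# Per-trial state -> dB calibration: returns list(c = dB per state unit,
# miss_offset_db = fallback additive offset on Miss trials).
#' @noRd
state_db_calibration <- function(config) {
  eff <- config$band_power_effect_db
  beta <- config$outcome_logit_slope
  if (eff == 0) return(list(c = 0, miss_offset_db = 0))
  if (beta == 0) return(list(c = 0, miss_offset_db = -eff))
  gap <- state_gap_choice_miss(stats::qlogis(config$miss_base_rate), beta)
  list(c = eff / gap, miss_offset_db = 0)
}

# Sharp-rise / slow-decay calcium kernel, unit L1 norm.
#' @noRd
calcium_kernel <- function(fs, tau_rise = 0.03, tau_decay = 0.3, dur = 2) {
  tt <- seq(0, dur, by = 1 / fs)
  k <- (1 - exp(-tt / tau_rise)) * exp(-tt / tau_decay)
  k / sum(k)
}

# Causal FFT convolution of x with kernel k, same length as x.
#' @noRd
conv_causal <- function(x, k) {
  n <- length(x) + length(k) - 1L
  y <- Re(stats::fft(stats::fft(c(x, rep(0, n - length(x)))) *
                     stats::fft(c(k, rep(0, n - length(k)))), inverse = TRUE)) / n
  y[seq_along(x)]
}

#' Generate the trial table and latent state of a synthetic session
#'
#' Trial timings follow the configured ranges (quiescent duration uniform,
#' go-cue delay uniform, one response-window duration per session); the
#' latent synchronization state is a per-trial AR(1) process with standard
#' normal marginal; each trial's outcome is drawn from a logistic model on
#' the trial's state.
#'
#' @param config a \code{sim_config}.
#' @param seed stream seed (defaults to a child of \code{config$seed}).
#' @return list with \code{trials} (data.frame, one row per trial: the event
#'   times, raw response fields, outcome, contrasts, labels) and
#'   \code{trial_state} (latent state per trial).
#' @export
generate_trials <- function(config, seed = child_seeds(config$seed, "trials")) {
  set.seed(as.integer(seed))
  n <- config$n_trials
  phi <- config$state_ar_coeff
  s <- numeric(n)
  s[1] <- stats::rnorm(1)
  if (n > 1) for (j in 2:n) s[j] <- phi * s[j - 1] + sqrt(1 - phi^2) * stats::rnorm(1)

  q <- stats::runif(n, config$quiescent_range_s[1], config$quiescent_range_s[2])
  pre <- stats::runif(n, 0.5, 3)                       # baseline before quiescence
  gocue_delay <- stats::runif(n, config$gocue_delay_range_s[1],
                              config$gocue_delay_range_s[2])
  rw <- stats::runif(1, config$response_window_s[1], config$response_window_s[2])

  lv <- config$contrast_levels
  nz <- lv[lv > 0]
  has_zero <- any(lv == 0)
  cl <- cr <- numeric(n)
  type <- character(n)
  for (j in seq_len(n)) {
    u <- stats::runif(1)
    if (has_zero && u < 0.2) {
      type[j] <- "zero"
    } else if (length(nz) && u < 0.3) {
      c0 <- sample(nz, 1); cl[j] <- c0; cr[j] <- c0; type[j] <- "equal"
    } else if (length(nz)) {
      c0 <- sample(nz, 1)
      if (stats::runif(1) < 0.5) cl[j] <- c0 else cr[j] <- c0
      type[j] <- "single"
    } else type[j] <- "zero"
  }

  b0 <- stats::qlogis(config$miss_base_rate)
  beta <- config$outcome_logit_slope
  outcome <- character(n)
  resp_dir <- integer(n)
  rt <- rep(NA_real_, n)
  rewarded <- logical(n)
  for (j in seq_len(n)) {
    if (type[j] == "zero") {
      fa <- stats::runif(1) < stats::plogis(stats::qlogis(0.3) - beta * s[j])
      if (fa) {
        outcome[j] <- "FalseAlarm"
        resp_dir[j] <- sample(c(-1L, 1L), 1)
        rt[j] <- min(0.2 + stats::rlnorm(1, log(0.3), 0.4), rw - 0.01)
      } else outcome[j] <- "CorrectReject"
    } else {
      miss <- stats::runif(1) < stats::plogis(b0 + beta * s[j])
      if (miss) {
        outcome[j] <- "Miss"
      } else {
        req <- sign(cr[j] - cl[j])
        if (req == 0) {                                  # equal contrast: random reward
          correct <- stats::runif(1) < 0.5
          resp_dir[j] <- sample(c(-1L, 1L), 1)
        } else {
          correct <- stats::runif(1) <
            stats::plogis(0.5 + 3 * abs(cr[j] - cl[j]))
          resp_dir[j] <- if (correct) req else -req
        }
        outcome[j] <- if (correct) "CorrectChoice" else "IncorrectChoice"
        rt[j] <- min(0.15 + 0.3 * (1 - max(cl[j], cr[j])) +
                       stats::rlnorm(1, log(0.2), 0.4), rw - 0.01)
      }
    }
  }
  rewarded <- outcome %in% c("CorrectChoice", "CorrectReject")

  iti_start <- quiescent_start <- stim_onset <- gocue <- resp_end <- numeric(n)
  response_s <- rep(NA_real_, n)
  t_cursor <- 0.5
  for (j in seq_len(n)) {
    iti_start[j] <- t_cursor
    quiescent_start[j] <- iti_start[j] + pre[j]
    stim_onset[j] <- quiescent_start[j] + q[j]
    gocue[j] <- stim_onset[j] + gocue_delay[j]
    resp_end[j] <- gocue[j] + rw
    if (!is.na(rt[j])) response_s[j] <- gocue[j] + rt[j]
    t_end <- if (!is.na(response_s[j])) response_s[j] else resp_end[j]
    t_cursor <- t_end + 1                                # feedback period
  }

  trials <- data.frame(
    trial = seq_len(n), iti_start_s = iti_start,
    quiescent_start_s = quiescent_start, quiescent_end_s = stim_onset,
    stim_onset_s = stim_onset, gocue_s = gocue,
    response_window_end_s = resp_end, response_s = response_s,
    response_direction = resp_dir, outcome = outcome,
    contrast_left = cl, contrast_right = cr, rewarded = rewarded,
    session_id = "synth01", subject_id = "mouse01", genotype_id = "g6s",
    stringsAsFactors = FALSE)
  list(trials = trials, trial_state = s)
}

# Per-master-frame latent state: each frame carries the state of the trial
# whose span [iti_start, next iti_start) contains it.
#' @noRd
frame_state <- function(tt, trials, trial_state) {
  idx <- findInterval(tt, trials$iti_start_s)
  idx[idx < 1L] <- 1L
  trial_state[idx]
}

#' Synthesize the dual-channel widefield movie
#'
#' Calcium channel: a smooth global spatial mode carrying 3-6 Hz band-limited
#' Gaussian noise whose amplitude is modulated by the latent state (in dB),
#' convolved with a sharp-rise/slow-decay calcium kernel; stimulus-locked
#' transient bumps; a constant baseline; the heartbeat-band artifact scaled
#' by the per-pixel gain map; white noise. Hemo channel: the gain-free
#' artifact plus independent white noise. The two channels are sampled on
#' interleaved timestamp grids offset by half a frame period.
#'
#' @param truth a \code{sim_truth} (from \code{\link{generate_session}}, or
#'   built internally).
#' @param trials trial table from \code{\link{generate_trials}}.
#' @param config the \code{sim_config}.
#' @param seed stream seed.
#' @return object of class \code{widefield_movie}: \code{calcium_frames} and
#'   \code{hemo_frames} (pixels x frames, row-major), \code{timestamps_cal},
#'   \code{timestamps_hemo}, \code{fs}, \code{pixel_shape}.
#' @export
synthesize_movie <- function(truth, trials, config,
                             seed = child_seeds(config$seed, "movie")) {
  set.seed(as.integer(seed))
  g <- config$grid_size; p <- g * g
  stop_if(length(truth$hemo_gain_map) != p,
          "gain map does not match the pixel grid")
  fs <- config$fs_channel; fs2 <- 2 * fs
  t_end <- max(trials$response_window_end_s) + 1.5
  n2 <- ceiling(t_end * fs2)
  tt <- (seq_len(n2) - 1) / fs2

  # state-modulated 3-6 Hz signal
  s_frame <- frame_state(tt, trials, truth$trial_state)
  x <- fft_bandpass(stats::rnorm(n2), fs2, 3, 6)
  x <- x / stats::sd(x)
  db <- truth$state_db_gain * s_frame
  if (truth$miss_offset_db != 0) {
    idx <- findInterval(tt, trials$iti_start_s)
    idx[idx < 1L] <- 1L
    db <- db + truth$miss_offset_db * (trials$outcome[idx] == "Miss")
  }
  # Kernel-filter the carrier first, then modulate: the injected per-trial
  # amplitude (hence the Choice - Miss dB effect) is exact, not smeared
  # across trial boundaries by the kernel tail.
  carrier <- conv_causal(x, calcium_kernel(fs2))
  carrier <- carrier / stats::sd(carrier)
  sig_state <- 3 * 10^(db / 20) * carrier

  # stimulus-locked transients (contralateral = right stimuli at VIS bump,
  # ipsilateral = left stimuli at the mirrored bump)
  stim_kernel <- function(tau) (1 - exp(-tau / 0.1)) * exp(-tau / 0.3)
  sig_vis_r <- numeric(n2); sig_vis_l <- numeric(n2)
  for (j in seq_len(nrow(trials))) {
    cmax_r <- trials$contrast_right[j]; cmax_l <- trials$contrast_left[j]
    if (cmax_r == 0 && cmax_l == 0) next
    i0 <- floor(trials$stim_onset_s[j] * fs2) + 1L
    i1 <- min(n2, i0 + ceiling(1.5 * fs2))
    if (i0 > n2) next
    tau <- tt[i0:i1] - trials$stim_onset_s[j]
    tc <- stim_kernel(pmax(tau, 0))
    sig_vis_r[i0:i1] <- sig_vis_r[i0:i1] + 8 * cmax_r * tc
    sig_vis_l[i0:i1] <- sig_vis_l[i0:i1] + 8 * cmax_l * tc
  }

  art <- fft_bandpass(stats::rnorm(n2), fs2,
                      config$heartbeat_hz - 1, config$heartbeat_hz + 1)
  art <- art / stats::sd(art)

  modes <- truth$spatial_modes
  cal_idx <- seq(1L, n2, by = 2L)
  hemo_idx <- seq(2L, n2, by = 2L)
  build <- function(idx) {
    outer(modes$state, sig_state[idx]) +
      outer(modes$vis, sig_vis_r[idx]) +
      outer(modes$vis_ipsi, sig_vis_l[idx]) +
      config$baseline_level
  }
  cal <- build(cal_idx) + outer(truth$hemo_gain_map, art[cal_idx])
  hemo <- matrix(rep(art[hemo_idx], each = p), nrow = p)
  if (config$noise_sd > 0) {
    cal <- cal + matrix(stats::rnorm(length(cal), 0, config$noise_sd), nrow = p)
    hemo <- hemo + matrix(stats::rnorm(length(hemo), 0, config$noise_sd), nrow = p)
  }
  structure(list(calcium_frames = cal, hemo_frames = hemo,
                 timestamps_cal = tt[cal_idx], timestamps_hemo = tt[hemo_idx],
                 fs = fs, pixel_shape = c(g, g)),
            class = "widefield_movie")
}

# Spatial modes and gain map for a g x g grid (deterministic).
#' @noRd
make_spatial_modes <- function(config) {
  g <- config$grid_size
  rows <- rep(seq_len(g) - 1L, each = g); cols <- rep(seq_len(g) - 1L, g)
  bump <- function(r0, c0, sigma) {
    m <- exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * sigma^2))
    m / max(m)
  }
  q <- max(1L, g %/% 4L)
  list(state = 0.4 + 0.6 * bump(g / 2 - 0.5, g / 2 - 0.5, g),
       vis = bump(q, q, g / 8), vis_ipsi = bump(q, 3 * q, g / 8))
}

#' @noRd
make_gain_map <- function(config) {
  g <- config$grid_size
  rows <- rep(seq_len(g) - 1L, each = g); cols <- rep(seq_len(g) - 1L, g)
  m <- exp(-((rows - g / 3)^2 + (cols - 2 * g / 3)^2) / (2 * (g / 3)^2))
  config$hemo_gain_map_scale * (0.4 + 0.6 * m / max(m))
}

#' Generate spikes, LFP and light onsets for a synthetic session
#'
#' Population spiking is an inhomogeneous Poisson process whose rate follows
#' the fluorescence at the VIS pixel, low-pass filtered below 8 Hz and
#' standardized; about a third of the units are contrast-tuned transient
#' units firing 50-150 ms after stimulus onset (state-independent, for
#' decoder tests). The LFP is the negated population rate plus noise, with
#' an optional light-pulse artifact at every illumination onset.
#'
#' @param truth a \code{sim_truth}.
#' @param movie the session's \code{widefield_movie}.
#' @param config the \code{sim_config}; \code{spike_coupling_gain} must be
#'   nonnegative.
#' @param trials trial table (stimulus onsets for the tuned units).
#' @param seed stream seed.
#' @return object of class \code{spike_data}: sorted \code{spike_times_s},
#'   \code{cluster_ids}, \code{cluster_depths} (um), \code{clusters}
#'   (data.frame: id, type, tuning), \code{lfp} (1 x time), \code{lfp_fs},
#'   \code{light_onsets_s}, and \code{n_rate_clipped}, the number of fine
#'   bins whose coupled rate was clipped at zero.
#' @export
generate_spike_data <- function(truth, movie, config, trials,
                                seed = child_seeds(config$seed, "spikes")) {
  stop_if(config$spike_coupling_gain < 0, "spike_coupling_gain must be >= 0")
  set.seed(as.integer(seed))
  fs <- movie$fs
  px <- pixel_index_raw(truth$coupling_pixel, config$grid_size)
  f <- movie$calcium_frames[px, ]
  f_lp <- fft_bandpass(f - mean(f), fs, 0, 8)
  z <- f_lp / stats::sd(f_lp)
  tcal <- movie$timestamps_cal

  dt <- 0.002
  t_end <- max(tcal)
  tg <- seq(0, t_end, by = dt)
  zg <- stats::approx(tcal, z, xout = tg, rule = 2)$y

  n_tuned <- max(4L, config$n_units %/% 3L)
  n_state <- config$n_units - n_tuned
  rate_pop <- 4 * n_state * (1 + config$spike_coupling_gain * zg)
  n_clip <- sum(rate_pop < 0)
  rate_pop[rate_pop < 0] <- 0

  times <- list(); ids <- list()
  counts <- stats::rpois(length(tg), rate_pop * dt)
  idx <- rep(seq_along(tg), counts)
  if (length(idx)) {
    times[[1]] <- tg[idx] + stats::runif(length(idx), 0, dt)
    ids[[1]] <- sample.int(n_state, length(idx), replace = TRUE)
  }

  tuning <- seq(0.5, 1.5, length.out = n_tuned)
  rate_tuned <- matrix(1, n_tuned, length(tg))       # 1 Hz base rate
  for (j in seq_len(nrow(trials))) {
    cr <- trials$contrast_right[j]
    if (cr == 0) next
    w <- tg >= trials$stim_onset_s[j] + 0.05 & tg < trials$stim_onset_s[j] + 0.15
    if (any(w)) rate_tuned[, w] <- rate_tuned[, w] + 40 * cr * tuning
  }
  for (u in seq_len(n_tuned)) {
    cnt <- stats::rpois(length(tg), rate_tuned[u, ] * dt)
    idx <- rep(seq_along(tg), cnt)
    if (length(idx)) {
      times[[length(times) + 1L]] <- tg[idx] + stats::runif(length(idx), 0, dt)
      ids[[length(ids) + 1L]] <- rep(n_state + u, length(idx))
    }
  }
  st <- unlist(times); ci <- unlist(ids)
  ord <- order(st)
  st <- st[ord]; ci <- as.integer(ci[ord])

  lfp_fs <- 700
  tl <- seq(0, t_end, by = 1 / lfp_fs)
  rate_l <- stats::approx(tg, rate_pop, xout = tl, rule = 2)$y
  lfp <- -(rate_l - mean(rate_l)) / stats::sd(rate_l) +
    stats::rnorm(length(tl), 0, 0.5)
  light_onsets <- sort(c(movie$timestamps_cal, movie$timestamps_hemo))
  if (config$light_artifact_amp > 0) {
    pulse <- config$light_artifact_amp * exp(-(0:6) / 2)
    for (on in light_onsets) {
      i0 <- floor(on * lfp_fs) + 1L
      i1 <- min(length(lfp), i0 + 6L)
      if (i0 <= length(lfp)) lfp[i0:i1] <- lfp[i0:i1] + pulse[seq_len(i1 - i0 + 1L)]
    }
  }
  clusters <- data.frame(id = seq_len(config$n_units),
                         type = c(rep("state", n_state), rep("tuned", n_tuned)),
                         tuning = c(rep(0, n_state), tuning))
  structure(list(spike_times_s = st, cluster_ids = ci,
                 cluster_depths = seq(200, 1000, length.out = config$n_units),
                 clusters = clusters,
                 lfp = matrix(lfp, nrow = 1), lfp_fs = lfp_fs,
                 lfp_timestamps_s = tl, light_onsets_s = light_onsets,
                 n_rate_clipped = n_clip),
            class = "spike_data")
}

# 0-based (row, col) -> 1-based row-major index without a store object
#' @noRd
pixel_index_raw <- function(coord, grid_size) {
  as.integer(coord[1] * grid_size + coord[2] + 1L)
}

#' Generate the pupil trace
#'
#' Pupil diameter is the latent state plus independent AR(1) noise, scaled so
#' the correlation with the state targets \code{pupil_state_corr}; the
#' derivative is the first difference over time.
#'
#' @param truth a \code{sim_truth}.
#' @param trials trial table.
#' @param config the \code{sim_config}.
#' @param timestamps sample times (the calcium frame times).
#' @param seed stream seed.
#' @return object of class \code{pupil_trace}: \code{timestamps_s},
#'   \code{diameter}, \code{derivative}.
#' @export
generate_pupil <- function(truth, trials, config, timestamps,
                           seed = child_seeds(config$seed, "pupil")) {
  set.seed(as.integer(seed))
  s <- frame_state(timestamps, trials, truth$trial_state)
  z_s <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s * 0
  n <- length(timestamps)
  e <- stats::rnorm(n)
  z_n <- stats::filter(e, 0.98, method = "recursive")
  z_n <- (z_n - mean(z_n)) / stats::sd(z_n)
  rho <- config$pupil_state_corr
  pup <- rho * z_s + sqrt(1 - rho^2) * as.numeric(z_n)
  diameter <- 3 + 0.5 * pup
  dtv <- c(NA_real_, diff(timestamps))
  derivative <- c(0, diff(diameter)) / ifelse(is.na(dtv), 1, dtv)
  structure(list(timestamps_s = timestamps, diameter = diameter,
                 derivative = derivative),
            class = "pupil_trace")
}

#' Generate a complete synthetic session
#'
#' Draws trials, latent state, movie, spikes, LFP and pupil from one root
#' seed via named child streams (trials / movie / spikes / pupil), so an
#' identical seed yields bit-identical outputs and each component can be
#' regenerated independently.
#'
#' @param config a \code{sim_config}.
#' @param include_spikes,include_pupil set FALSE to skip generating the
#'   spike/LFP or pupil components (NULL in the output); the child-stream
#'   seeding guarantees the other components are unchanged.
#' @return list with \code{movie} (\code{widefield_movie}), \code{trials}
#'   (trial table data.frame), \code{spikes} (\code{spike_data}),
#'   \code{pupil} (\code{pupil_trace}) and \code{truth} (\code{sim_truth}:
#'   \code{latent_state} per calcium frame, \code{trial_state},
#'   \code{hemo_gain_map} as a matrix, \code{true_effect_db},
#'   \code{true_outcome_slope}, \code{spatial_modes}, the state-to-dB gain
#'   and the coupling pixel).
#' @export
generate_session <- function(config, include_spikes = TRUE,
                             include_pupil = TRUE) {
  stop_if(config$quiescent_range_s[2] < 0.7,
          "all quiescent periods would be below the 0.7 s inclusion minimum")
  if (config$quiescent_range_s[1] < 0.7) {
    warning("quiescent minimum below 0.7 s: some trials will be excluded downstream",
            call. = FALSE)
  }
  seeds <- child_seeds(config$seed, c("trials", "movie", "spikes", "pupil"))
  tr <- generate_trials(config, seeds[["trials"]])
  calib <- state_db_calibration(config)
  g <- config$grid_size
  q <- max(1L, g %/% 4L)
  truth <- structure(list(trial_state = tr$trial_state,
                          hemo_gain_map = make_gain_map(config),
                          true_effect_db = config$band_power_effect_db,
                          true_outcome_slope = config$outcome_logit_slope,
                          spatial_modes = make_spatial_modes(config),
                          state_db_gain = calib$c,
                          miss_offset_db = calib$miss_offset_db,
                          coupling_pixel = c(q, q)),
                     class = "sim_truth")
  movie <- synthesize_movie(truth, tr$trials, config, seeds[["movie"]])
  spikes <- if (include_spikes)
    generate_spike_data(truth, movie, config, tr$trials, seeds[["spikes"]])
  pupil <- if (include_pupil)
    generate_pupil(truth, tr$trials, config, movie$timestamps_cal,
                   seeds[["pupil"]])
  truth$latent_state <- frame_state(movie$timestamps_cal, tr$trials,
                                    tr$trial_state)
  truth$hemo_gain_map <- matrix(truth$hemo_gain_map, g, g, byrow = TRUE)
  list(movie = movie, trials = tr$trials, spikes = spikes, pupil = pupil,
       truth = truth)
}

#' Simulate a multi-session band-power table with nested random effects
#'
#' Generates per-trial, per-area band power (in dB) with random
#' genotype/subject/session offsets and slopes by area, plus an optional
#' condition effect, matching the generative assumptions of
#' \code{\link{fit_state_mixed_model}}. This is the validation procedure for
#' the nested mixed-effects test: simulate data with random differences
#' between mice, sessions and genotypes but a known (possibly zero)
#' condition effect, and check what the test reports.
#'
#' @param n_genotypes,subjects_per_genotype,sessions_per_subject,trials_per_session
#'   design sizes.
#' @param areas character vector of area names.
#' @param cond_effect_db additive power difference (dB) for Miss trials.
#' @param sd_genotype,sd_subject,sd_session SDs of the random area-specific
#'   offsets at each nesting level.
#' @param sd_noise residual SD (dB).
#' @param miss_rate proportion of Miss trials.
#' @param seed integer seed.
#' @return data.frame in long format: power_db, cond, area, genotype_id,
#'   subject_id, session_id, trial.
#' @export
simulate_band_power_table <- function(n_genotypes = 3, subjects_per_genotype = 2,
                                      sessions_per_subject = 2,
                                      trials_per_session = 50,
                                      areas = c("VIS", "SS", "AUD", "RSP", "MO"),
                                      cond_effect_db = 0,
                                      sd_genotype = 0.5, sd_subject = 0.5,
                                      sd_session = 0.5, sd_noise = 1.5,
                                      miss_rate = 0.3, seed = 1L) {
  set.seed(as.integer(seed))
  na <- length(areas)
  rows <- list()
  for (gi in seq_len(n_genotypes)) {
    off_g <- stats::rnorm(na, 0, sd_genotype)
    for (si in seq_len(subjects_per_genotype)) {
      off_s <- stats::rnorm(na, 0, sd_subject)
      for (ei in seq_len(sessions_per_subject)) {
        off_e <- stats::rnorm(na, 0, sd_session)
        n <- trials_per_session
        cond <- ifelse(stats::runif(n) < miss_rate, "Miss", "Choice")
        for (ai in seq_len(na)) {
          rows[[length(rows) + 1L]] <- data.frame(
            power_db = off_g[ai] + off_s[ai] + off_e[ai] +
              cond_effect_db * (cond == "Miss") +
              stats::rnorm(n, 0, sd_noise),
            cond = cond, area = areas[ai],
            genotype_id = sprintf("g%02d", gi),
            subject_id = sprintf("g%02d_m%02d", gi, si),
            session_id = sprintf("g%02d_m%02d_s%02d", gi, si, ei),
            trial = seq_len(n), stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
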