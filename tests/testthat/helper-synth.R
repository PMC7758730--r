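# Shared fixtures, all generated in code. Sessions are cached per
# configuration key so multiple test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached_session <- function(key, ...) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- suppressWarnings(suppressMessages(
      generate_session(sim_config(...))))
  }
  .fixture_cache[[key]]
}

# Default small session used across modules
small_session <- function() {
  cached_session("small", n_trials = 60, seed = 11)
}

small_session_stores <- function(k_cal = 60, k_hemo = 20) {
  key <- sprintf("small_stores_%d_%d", k_cal, k_hemo)
  if (is.null(.fixture_cache[[key]])) {
    s <- small_session()
    .fixture_cache[[key]] <- list(
      cal = compress_movie(s$movie$calcium_frames, s$movie$timestamps_cal,
                           k = k_cal, channel = "calcium"),
      hemo = compress_movie(s$movie$hemo_frames, s$movie$timestamps_hemo,
                            k = k_hemo, channel = "hemo"))
  }
  .fixture_cache[[key]]
}

# Small random movie matrix with a fixed seed
toy_movie <- function(pixels, frames, seed = 1, fs = 35) {
  set.seed(seed)
  list(frames = matrix(rnorm(pixels * frames), pixels, frames),
       timestamps = (seq_len(frames) - 1) / fs, fs = fs)
}

# Dense per-pixel band-power oracle: periodogram of each pixel trace with
# the same one-sided power normalization as component_spectra.
oracle_band_power <- function(frames, fs, band) {
  n <- ncol(frames)
  nf <- floor(n / 2) + 1L
  freqs <- (seq_len(nf) - 1) * fs / n
  mult <- rep(2, nf); mult[1] <- 1
  if (n %% 2 == 0) mult[nf] <- 1
  sel <- freqs >= band[1] & freqs <= band[2]
  apply(frames, 1, function(x) {
    fx <- fft(x)[seq_len(nf)] / n
    sum(mult[sel] * Mod(fx[sel])^2)
  })
}

# Pixel-space oracle for the hemo gain of one pixel: detrend, high-pass,
# band-pass (same FFT filters, applied to the dense traces), then a
# no-intercept regression.
oracle_hemo_gain <- function(cal_trace, hemo_trace_aligned, fs, band = c(9, 13),
                             hp = 0.01) {
  filt <- function(x) {
    x <- cortexstate:::detrend_linear(x)
    x <- cortexstate:::fft_bandpass(x, fs, hp, Inf)
    cortexstate:::fft_bandpass(x, fs, band[1], band[2])
  }
  a <- filt(cal_trace); b <- filt(hemo_trace_aligned)
  sum(a * b) / sum(b * b)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)) / max(abs(expected), 1e-300), tol)
}
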