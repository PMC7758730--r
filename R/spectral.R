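# Spectral analysis in the compressed (SVD) domain.
#
# For pixel n the fluorescence is f_n(t) = U[n, ] %*% V, so its Fourier
# transform is fhat_n(w) = sum_i U[n, i] * Vhat_i(w): transforming the k
# temporal components once gives the spectrum of every pixel by matrix
# multiplication, and band power for all pixels is assembled from a k x k
# cross-spectral matrix without ever materializing the pixel x time movie.

#' Fourier transforms of the temporal components over a window
#'
#' Computes the one-sided discrete Fourier transform of each row of V over a
#' half-open time window. Normalization: \code{vhat = fft(v)/N} at one-sided
#' frequencies, with a fold multiplier of 2 for all bins except DC and
#' Nyquist, so that \code{sum(mult * |vhat|^2)} equals the mean square of the
#' windowed signal (power, not density; Parseval).
#'
#' @param store an \code{svd_store}.
#' @param window half-open (start, end) window in seconds; NULL for all frames.
#' @param taper "rect" (default; band sums stay literal over the short
#'   quiescent windows this package targets) or "hann".
#' @param demean subtract each component's window mean before transforming
#'   (default FALSE; the 3-6 Hz band excludes DC anyway).
#' @return object of class \code{component_spectra}: complex matrix
#'   \code{vhat} (k x n_freq), \code{freqs_hz}, fold multipliers \code{mult},
#'   window metadata.
#' @export
component_spectra <- function(store, window = NULL, taper = c("rect", "hann"),
                              demean = FALSE) {
  taper <- match.arg(taper)
  cols <- if (is.null(window)) seq_len(ncol(store$V)) else
    frames_in_window(store$timestamps, window)
  stop_if(length(cols) < 2L, "window must contain at least 2 samples")
  Vw <- store$V[, cols, drop = FALSE]
  if (demean) Vw <- Vw - rowMeans(Vw)
  n <- ncol(Vw)
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    w <- w / sqrt(mean(w^2))               # preserve mean-square normalization
    Vw <- Vw * rep(w, each = nrow(Vw))
  }
  fs <- store_fs(store)
  nf <- floor(n / 2) + 1L
  vhat <- t(stats::mvfft(t(Vw)))[, seq_len(nf), drop = FALSE] / n
  mult <- rep(2, nf)
  mult[1] <- 1
  if (n %% 2 == 0) mult[nf] <- 1           # Nyquist bin present only for even n
  structure(list(vhat = vhat, freqs_hz = (seq_len(nf) - 1) * fs / n,
                 mult = mult, n = n, fs = fs, window = window, taper = taper),
            class = "component_spectra")
}

# k x k band cross-spectral matrix C = sum_{w in band} mult_w Re(vhat vhat^H),
# so that pixel band power is rowSums((U %*% C) * U).
#' @noRd
band_cross_spectrum <- function(spec, band_hz) {
  tol <- 1e-6 * spec$fs / spec$n           # guard band edges against FP jitter
  sel <- spec$freqs_hz >= band_hz[1] - tol & spec$freqs_hz <= band_hz[2] + tol
  if (!any(sel)) {
    stop(sprintf(paste0("no frequency bin falls in [%g, %g] Hz: bin spacing is ",
                        "%.3f Hz; use a window of at least %.2f s"),
                 band_hz[1], band_hz[2], spec$fs / spec$n,
                 1 / (band_hz[2] - band_hz[1])), call. = FALSE)
  }
  Vb <- spec$vhat[, sel, drop = FALSE]
  Vbm <- Vb * rep(spec$mult[sel], each = nrow(Vb))
  Re(Vbm %*% Conj(t(Vb)))
}

#' Per-pixel band power map over one time window
#'
#' Band power at pixel n is \code{sum_w mult_w |sum_i U[n,i] Vhat_i(w)|^2}
#' over the frequency bins with \code{low <= f <= high} (inclusive band
#' edges; with 0.7 s windows the bin spacing is about 1.4 Hz, so inclusivity
#' matters and is fixed here). Cost is O(k^2 bins + pixels k^2).
#'
#' @param store an \code{svd_store}.
#' @param window half-open (start, end) in seconds; NULL for all frames.
#' @param band_hz (low, high) band in Hz, within (0, Nyquist].
#' @param taper,demean passed to \code{\link{component_spectra}}.
#' @return object of class \code{power_map}: matrix \code{power}
#'   (rows x cols, a.u.^2, nonnegative), \code{band_hz},
#'   \code{n_trials_averaged}, and \code{avg_power}, the per-pixel
#'   time-averaged broadband power used for masking difference maps.
#' @export
compute_power_map <- function(store, window = NULL, band_hz = c(3, 6),
                              taper = "rect", demean = FALSE) {
  nyq <- store_fs(store) / 2
  stop_if(band_hz[1] <= 0 || band_hz[2] > nyq + 1e-9 || band_hz[1] > band_hz[2],
          "band must lie within (0, Nyquist]")
  spec <- component_spectra(store, window, taper = taper, demean = demean)
  C <- band_cross_spectrum(spec, band_hz)
  p <- rowSums((store$U %*% C) * store$U)
  p[p < 0] <- 0                            # numerical floor
  cols <- if (is.null(window)) seq_len(ncol(store$V)) else
    frames_in_window(store$timestamps, window)
  Vw <- store$V[, cols, drop = FALSE]
  Cv <- Vw %*% t(Vw) / ncol(Vw)
  avg <- rowSums((store$U %*% Cv) * store$U)
  structure(list(power = matrix(p, store$pixel_shape[1], store$pixel_shape[2],
                                byrow = TRUE),
                 avg_power = matrix(avg, store$pixel_shape[1],
                                    store$pixel_shape[2], byrow = TRUE),
                 band_hz = band_hz, n_trials_averaged = 1L,
                 pixel_shape = store$pixel_shape),
            class = "power_map")
}

#' Average band power map over a set of trial windows
#'
#' Computes \code{\link{compute_power_map}} per window and averages, e.g. the
#' mean quiescent-period 3-6 Hz power map over all Choice trials.
#'
#' @param store an \code{svd_store}.
#' @param windows list of half-open (start, end) windows in seconds.
#' @param band_hz,taper,demean as in \code{\link{compute_power_map}}.
#' @return a \code{power_map} with \code{n_trials_averaged = length(windows)}.
#' @export
average_power_map <- function(store, windows, band_hz = c(3, 6),
                              taper = "rect", demean = FALSE) {
  stop_if(length(windows) == 0L, "no windows supplied")
  maps <- lapply(windows, function(w)
    compute_power_map(store, w, band_hz, taper = taper, demean = demean))
  out <- maps[[1]]
  out$power <- Reduce(`+`, lapply(maps, `[[`, "power")) / length(maps)
  out$avg_power <- Reduce(`+`, lapply(maps, `[[`, "avg_power")) / length(maps)
  out$n_trials_averaged <- length(windows)
  out
}

#' Band power of one ROI pixel over many windows
#'
#' Returns, for each window, the band power of the ROI pixel's reconstructed
#' trace; identical to reading \code{compute_power_map} at that pixel but
#' O(k) per window instead of O(pixels k^2).
#'
#' @param store an \code{svd_store}.
#' @param roi 0-based (row, col) pixel coordinate.
#' @param windows list of half-open (start, end) windows in seconds.
#' @param band_hz (low, high) in Hz.
#' @param taper "rect" or "hann".
#' @return numeric vector of band powers (a.u.^2), one per window.
#' @export
roi_band_power <- function(store, roi, windows, band_hz = c(3, 6),
                           taper = "rect") {
  idx <- pixel_index(store, roi[1], roi[2])
  u <- store$U[idx, , drop = FALSE]
  vapply(windows, function(w) {
    spec <- component_spectra(store, w, taper = taper)
    tol <- 1e-6 * spec$fs / spec$n
    sel <- spec$freqs_hz >= band_hz[1] - tol & spec$freqs_hz <= band_hz[2] + tol
    if (!any(sel)) {
      stop(sprintf("no frequency bin in band for a %.3f s window; need >= %.2f s",
                   diff(range(w)), 1 / (band_hz[2] - band_hz[1])), call. = FALSE)
    }
    fhat <- u %*% spec$vhat[, sel, drop = FALSE]
    sum(spec$mult[sel] * Mod(fhat)^2)
  }, numeric(1))
}

#' Condition difference map in decibels
#'
#' P_diff(x, y) = 10 log10(P_a / P_b): the per-pixel power ratio between two
#' condition-average maps (e.g. Choice vs Miss) in dB. Pixels whose
#' time-averaged broadband power falls below \code{mask_percentile} of all
#' pixels are masked (this removes pixels outside the brain in real data);
#' zero-denominator pixels are masked and flagged rather than returned
#' infinite.
#'
#' @param map_a,map_b \code{power_map} objects on the same grid and band
#'   (numerator, denominator).
#' @param mask_percentile percentile (0-100) of time-averaged power below
#'   which pixels are masked; default 20.
#' @return object of class \code{diff_map}: matrix \code{diff_db} (NA where
#'   masked), logical \code{mask}, \code{conditions}, and
#'   \code{n_zero_denominator}.
#' @export
diff_map_db <- function(map_a, map_b, mask_percentile = 20,
                        conditions = c("a", "b")) {
  stop_if(!identical(dim(map_a$power), dim(map_b$power)), "grid mismatch")
  stop_if(!isTRUE(all.equal(map_a$band_hz, map_b$band_hz)), "band mismatch")
  avg <- (map_a$avg_power + map_b$avg_power) / 2
  thr <- stats::quantile(avg, mask_percentile / 100, names = FALSE)
  mask <- avg < thr
  zero_den <- map_b$power <= 0 | map_a$power <= 0
  mask <- mask | zero_den
  db <- matrix(NA_real_, nrow(map_a$power), ncol(map_a$power))
  ok <- !mask
  db[ok] <- 10 * log10(map_a$power[ok] / map_b$power[ok])
  structure(list(diff_db = db, mask = mask, conditions = conditions,
                 band_hz = map_a$band_hz, n_zero_denominator = sum(zero_den)),
            class = "diff_map")
}

#' Stimulus-triggered response map
#'
#' For each selected trial, takes the mean frame in a post-stimulus response
#' window (default 70-80 ms, where the GCaMP6s rise gives the cleanest
#' response) minus the immediately preceding frame, and averages over trials.
#' Baseline subtraction at stimulus onset cancels in the frame difference.
#' Computed in compressed space (one U multiply at the end).
#'
#' @param store an \code{svd_store}.
#' @param trials a trial table (see \code{\link{generate_session}}) with
#'   \code{stim_onset_s}.
#' @param selector logical vector over trials, or a function of the trial
#'   table returning one (e.g. \code{function(tr) tr$contrast_right >= 0.5}).
#' @param response_window_ms (start, end) in ms post stimulus onset.
#' @return list with matrix \code{response} (rows x cols) and \code{n_trials}.
#' @export
stim_triggered_map <- function(store, trials, selector,
                               response_window_ms = c(70, 80)) {
  sel <- if (is.function(selector)) selector(trials) else as.logical(selector)
  sel[is.na(sel)] <- FALSE
  stop_if(sum(sel) == 0L, "selector matches no trials")
  ts <- store$timestamps
  vdiff <- numeric(nrow(store$V))
  n_used <- 0L
  for (t0 in trials$stim_onset_s[sel]) {
    lo <- t0 + response_window_ms[1] / 1000
    hi <- t0 + response_window_ms[2] / 1000
    resp <- which(ts >= lo & ts <= hi)
    if (length(resp) == 0L) resp <- which.min(abs(ts - (lo + hi) / 2))
    prev <- min(resp) - 1L
    if (prev < 1L) next
    v_resp <- rowMeans(store$V[, resp, drop = FALSE])
    vdiff <- vdiff + (v_resp - store$V[, prev])
    n_used <- n_used + 1L
  }
  stop_if(n_used == 0L, "no selected trial has frames in the response window")
  resp <- drop(store$U %*% (vdiff / n_used))
  list(response = matrix(resp, store$pixel_shape[1], store$pixel_shape[2],
                         byrow = TRUE),
       n_trials = n_used, response_window_ms = response_window_ms)
}
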