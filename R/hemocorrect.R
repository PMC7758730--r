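# Hemodynamic correction.
#
# Blood volume/oxygenation changes contaminate the calcium-dependent
# fluorescence channel; the contamination is strongest in the heartbeat band
# (9-13 Hz). A calcium-independent illumination channel measures it
# directly, and the correction subtracts a per-pixel multiple of that
# channel from the calcium channel. The multiple is estimated by linear
# regression of the filtered calcium trace on the equivalently filtered,
# time-aligned hemo trace, and both estimation and subtraction run entirely
# in the SVD domain.

# Filter chain used for gain estimation: linear detrend, 0.01 Hz high-pass,
# then heartbeat band-pass. Zero-phase FFT-domain filters (see ledger note:
# exact zero phase; the paper names bands, not a filter family).
#' @noRd
hemo_filter_rows <- function(V, fs, band, highpass_hz) {
  V <- detrend_linear(V)
  V <- fft_bandpass(V, fs, low = highpass_hz, high = Inf)
  fft_bandpass(V, fs, low = band[1], high = band[2])
}

# Interpolate the rows of a hemo store's V onto the calcium timestamps.
# Alternate-frame illumination offsets the channels by half a frame period;
# at 35 Hz a linear interpolant would attenuate the 9-13 Hz heartbeat band
# by cos(pi f / fs) (about 0.55 at 11 Hz) and inflate the regression gains
# by its reciprocal, so for uniform interleaved grids the shift is done by
# exact bandlimited (FFT phase-ramp) interpolation; non-uniform grids fall
# back to linear.
#' @noRd
align_hemo_V <- function(hemo, timestamps) {
  th <- hemo$timestamps
  dth <- diff(th)
  uniform <- length(th) > 3 &&
    max(abs(dth - dth[1])) < 1e-6 * dth[1] &&
    abs(length(timestamps) - length(th)) <= 1L
  if (uniform) {
    n <- length(th)
    m <- min(n, length(timestamps))
    delta <- mean(th[seq_len(m)] - timestamps[seq_len(m)])   # hemo lags cal
    f <- seq(0, n - 1) / n
    f <- ifelse(f > 0.5, f - 1, f) / dth[1]                  # two-sided Hz
    ramp <- exp(-2i * pi * f * delta)
    Vs <- Re(t(stats::mvfft(t(t(stats::mvfft(t(hemo$V))) * rep(ramp, each = nrow(hemo$V))),
                            inverse = TRUE))) / n
    out <- matrix(0, nrow(hemo$V), length(timestamps))
    out[, seq_len(m)] <- Vs[, seq_len(m)]
    if (length(timestamps) > n) out[, length(timestamps)] <- Vs[, n]
    return(out)
  }
  t(apply(hemo$V, 1L, function(v)
    stats::approx(th, v, xout = timestamps, rule = 2)$y))
}

#' Estimate per-pixel hemodynamic regression gains
#'
#' For every pixel, the gain is the no-intercept least-squares coefficient of
#' the detrended, 0.01 Hz high-passed, heartbeat-band-passed calcium trace on
#' the equivalently filtered, time-aligned hemo trace. The per-pixel
#' regressions are assembled from k x k component cross-products (filters act
#' on V only), never by materializing pixel traces. No intercept is fitted:
#' the filtered signals are zero-mean by construction.
#'
#' @param cal calcium-channel \code{svd_store}.
#' @param hemo hemo-channel \code{svd_store} on the same pixel grid,
#'   timestamps interleaved with the calcium channel.
#' @param band_hz heartbeat band (default c(9, 13)).
#' @param highpass_hz high-pass edge applied before band-passing (default 0.01).
#' @return object of class \code{hemo_gain_map}: matrix \code{gain}
#'   (rows x cols), \code{diagnostics} (per-pixel residual heartbeat-band
#'   power fraction in [0, 1]), logical \code{degenerate} flagging pixels
#'   with zero-variance hemo band signal (gain forced to 0), and the band
#'   metadata.
#' @export
estimate_hemo_gains <- function(cal, hemo, band_hz = c(9, 13),
                                highpass_hz = 0.01) {
  stop_if(!identical(cal$pixel_shape, hemo$pixel_shape),
          "calcium and hemo stores are on different pixel grids")
  fs <- store_fs(cal)
  stop_if(band_hz[2] > fs / 2 + 1e-9,
          "heartbeat band exceeds the channel Nyquist frequency")
  Vh <- align_hemo_V(hemo, cal$timestamps)
  Vcf <- hemo_filter_rows(cal$V, fs, band_hz, highpass_hz)
  Vhf <- hemo_filter_rows(Vh, fs, band_hz, highpass_hz)
  C_ch <- Vcf %*% t(Vhf)
  C_hh <- Vhf %*% t(Vhf)
  C_cc <- Vcf %*% t(Vcf)
  num <- rowSums((cal$U %*% C_ch) * hemo$U)
  den <- rowSums((hemo$U %*% C_hh) * hemo$U)
  cal_band <- rowSums((cal$U %*% C_cc) * cal$U)
  degenerate <- den <= .Machine$double.eps * max(den, 1)
  gain <- ifelse(degenerate, 0, num / ifelse(degenerate, 1, den))
  # residual band power after subtraction: c - 2 g ch + g^2 h
  resid <- cal_band - 2 * gain * num + gain^2 * den
  frac <- ifelse(cal_band > 0, pmin(pmax(resid / cal_band, 0), 1), 0)
  shp <- cal$pixel_shape
  structure(list(gain = matrix(gain, shp[1], shp[2], byrow = TRUE),
                 diagnostics = matrix(frac, shp[1], shp[2], byrow = TRUE),
                 degenerate = matrix(degenerate, shp[1], shp[2], byrow = TRUE),
                 band_hz = band_hz, highpass_hz = highpass_hz),
            class = "hemo_gain_map")
}

#' Apply hemodynamic correction in the SVD domain
#'
#' Returns a store representing \code{cal - gain (.) hemo_aligned}: the
#' per-pixel multiple of the raw (unfiltered) hemo signal, interpolated onto
#' the calcium timestamps, is subtracted from the calcium channel. The
#' filtering in \code{\link{estimate_hemo_gains}} exists only to estimate the
#' multiple. The difference is refactorized (QR then small SVD) so the result
#' is a proper store of rank at most k_cal + k_hemo; the pixel x time movie
#' is never formed.
#'
#' With \code{gains = NULL} the calcium store is passed through untouched and
#' tagged "uncorrected" (for sessions recorded without a hemo channel).
#'
#' @param cal calcium-channel \code{svd_store}.
#' @param hemo hemo-channel \code{svd_store} (same grid).
#' @param gains a \code{hemo_gain_map} from the same session, or NULL for
#'   pass-through.
#' @return an \code{svd_store} with channel tag "corrected" (or
#'   "uncorrected" for pass-through).
#' @export
apply_hemo_correction <- function(cal, hemo, gains) {
  if (is.null(gains)) {
    out <- cal
    out$channel <- "uncorrected"
    return(out)
  }
  stop_if(!identical(cal$pixel_shape, hemo$pixel_shape), "grid mismatch")
  g <- as.vector(t(gains$gain))            # row-major pixel order
  stop_if(length(g) != nrow(cal$U), "gain map does not match the pixel grid")
  Vh <- align_hemo_V(hemo, cal$timestamps)
  Ug <- cbind(cal$U, hemo$U * g)           # p x (k1 + k2)
  Vg <- rbind(cal$V, -Vh)
  qrd <- qr(Ug)
  R <- qr.R(qrd)
  dec <- svd(R %*% Vg)
  keep <- which(dec$d > max(dec$d[1], 0) * 1e-12)
  if (length(keep) == 0L) keep <- 1L
  U_new <- qr.Q(qrd) %*% dec$u[, keep, drop = FALSE]
  V_new <- t(dec$v[, keep, drop = FALSE]) * dec$d[keep]
  for (j in seq_along(keep)) {             # sign convention, as in compress_movie
    i <- which.max(abs(U_new[, j]))
    if (U_new[i, j] < 0) { U_new[, j] <- -U_new[, j]; V_new[j, ] <- -V_new[j, ] }
  }
  svd_store(U_new, V_new, dec$d[keep], cal$timestamps, cal$pixel_shape,
            channel = "corrected")
}
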