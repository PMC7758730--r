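# Spike / LFP state measures and the bridge to the imaging signal.

#' Bin and smooth multiunit activity
#'
#' Histograms all spikes at 1/fs_out bins (counts conserve the total spike
#' count exactly), converts to rate, and smooths with a normalized Gaussian
#' window (mean rate preserved). 35 Hz matches the imaging frame rate so the
#' MUA trace can be analysed identically to a pixel trace.
#'
#' @param spikes a \code{spike_data} (or any list with spike_times_s).
#' @param fs_out output sampling rate in Hz (default 35).
#' @param smoothing_sd_s Gaussian SD in seconds (default 0.025).
#' @param t_range (start, end) of the binning grid; defaults to (0, last
#'   spike).
#' @return object of class \code{mua_trace}: \code{rate} (spikes/s),
#'   \code{timestamps_s} (bin centers), \code{counts} (pre-smoothing),
#'   \code{fs}, \code{smoothing_sd_s}.
#' @export
bin_and_smooth_mua <- function(spikes, fs_out = 35, smoothing_sd_s = 0.025,
                               t_range = NULL) {
  st <- spikes$spike_times_s
  if (length(st) == 0L) {
    warning("empty spike train: returning a zero trace", call. = FALSE)
    st <- numeric()
  }
  if (is.null(t_range)) t_range <- c(0, if (length(st)) max(st) else 1)
  edges <- seq(t_range[1], t_range[2] + 1 / fs_out, by = 1 / fs_out)
  counts <- if (length(st)) bin_counts_edges(st, edges)
  else rep(0L, length(edges) - 1L)
  rate <- counts * fs_out
  if (smoothing_sd_s > 0) {
    half <- max(1L, ceiling(4 * smoothing_sd_s * fs_out))
    kt <- (-half:half) / fs_out
    k <- exp(-kt^2 / (2 * smoothing_sd_s^2))
    k <- k / sum(k)
    n <- length(rate)
    padded <- c(rep(rate[1], half), rate, rep(rate[n], half))
    rate <- stats::convolve(padded, rev(k), type = "filter")
  }
  structure(list(rate = pmax(rate, 0),
                 timestamps_s = edges[-length(edges)] + 1 / (2 * fs_out),
                 counts = counts, fs = fs_out, smoothing_sd_s = smoothing_sd_s),
            class = "mua_trace")
}

#' Remove the illumination light artifact from an LFP trace
#'
#' Light onsets of one illumination color inject a stereotyped artifact.
#' For every onset the trace segment is aligned, its baseline (the sample
#' before the onset) subtracted, and a running median over
#' \code{n_median} pulses forms the artifact template, which is subtracted
#' back at each onset. Segments truncated by the next onset are handled and
#' flagged.
#'
#' @param lfp numeric LFP trace (one channel).
#' @param light_onsets_s onset times of one illumination color, seconds.
#' @param fs LFP sampling rate, Hz.
#' @param segment_s aligned segment duration after each onset (default
#'   0.01 s).
#' @param n_median running-median width in pulses (default 500).
#' @return list: \code{lfp} (cleaned trace), \code{n_truncated}.
#' @export
remove_light_artifact <- function(lfp, light_onsets_s, fs, segment_s = 0.01,
                                  n_median = 500L) {
  stop_if(length(light_onsets_s) < 1L, "at least one light onset required")
  lfp <- as.numeric(lfp)
  seg_len <- max(1L, round(segment_s * fs))
  on_idx <- floor(light_onsets_s * fs) + 1L
  on_idx <- on_idx[on_idx >= 2L & on_idx <= length(lfp)]
  n <- length(on_idx)
  seg <- matrix(NA_real_, n, seg_len)
  truncated <- 0L
  for (i in seq_len(n)) {
    last <- min(on_idx[i] + seg_len - 1L, length(lfp),
                if (i < n) on_idx[i + 1L] - 1L else Inf)
    len <- last - on_idx[i] + 1L
    if (len < seg_len) truncated <- truncated + 1L
    seg[i, seq_len(len)] <- lfp[on_idx[i]:last] - lfp[on_idx[i] - 1L]
  }
  if (truncated > 0L) {
    message(truncated, " light-pulse segment(s) truncated by the next onset")
  }
  half <- max(1L, n_median %/% 2L)
  cleaned <- lfp
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    template <- apply(seg[lo:hi, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    len <- sum(!is.na(seg[i, ]))
    idx <- on_idx[i]:(on_idx[i] + len - 1L)
    cleaned[idx] <- cleaned[idx] - template[seq_len(len)]
  }
  list(lfp = cleaned, n_truncated = truncated)
}

#' Fano factor of population spike counts per trial window
#'
#' For each window, all spikes (the summed population) are counted in
#' sub-bins of width \code{bin_s} tiling the window, and
#' F = var(X) / mean(X) over those counts (sample variance, n - 1
#' denominator). Windows with zero mean count are flagged NA. The ensemble
#' over which var and mean are taken is configurable: "bins" (the default
#' tiling described above) or "trials" (one count per window, F computed
#' across all windows, returned as a scalar).
#'
#' @param spikes a \code{spike_data}.
#' @param windows list of half-open (start, end) windows in seconds (e.g.
#'   quiescent periods, the same windows used for band power).
#' @param bin_s sub-bin width (default 1/35 s, one imaging frame).
#' @param ensemble "bins" or "trials".
#' @param var_denominator "n-1" (sample variance, default) or "n".
#' @return object of class \code{fano_result}: \code{fano} per window (or
#'   scalar for ensemble = "trials"), \code{spike_count} per window,
#'   \code{undefined} logical flags, plus the window list.
#' @export
fano_factor <- function(spikes, windows, bin_s = 1 / 35,
                        ensemble = c("bins", "trials"),
                        var_denominator = c("n-1", "n")) {
  ensemble <- match.arg(ensemble)
  var_denominator <- match.arg(var_denominator)
  st <- spikes$spike_times_s
  vf <- function(x) {
    v <- stats::var(x)
    if (var_denominator == "n") v <- v * (length(x) - 1) / length(x)
    v
  }
  total <- vapply(windows, function(w) sum(st >= w[1] & st < w[2]), numeric(1))
  if (ensemble == "trials") {
    if (mean(total) == 0) {
      warning("zero mean count: Fano factor undefined", call. = FALSE)
      return(structure(list(fano = NA_real_, spike_count = total,
                            undefined = TRUE, windows = windows),
                       class = "fano_result"))
    }
    return(structure(list(fano = vf(total) / mean(total), spike_count = total,
                          undefined = FALSE, windows = windows),
                     class = "fano_result"))
  }
  fano <- rep(NA_real_, length(windows))
  undefined <- rep(TRUE, length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    nb <- floor((w[2] - w[1]) / bin_s)
    if (nb < 2L) next
    edges <- w[1] + (0:nb) * bin_s
    x <- bin_counts_edges(st, edges)
    if (mean(x) > 0) {
      fano[i] <- vf(x) / mean(x)
      undefined[i] <- FALSE
    }
  }
  if (any(undefined)) {
    message(sum(undefined), " window(s) with zero mean count flagged undefined")
  }
  structure(list(fano = fano, spike_count = total, undefined = undefined,
                 windows = windows, bin_s = bin_s),
            class = "fano_result")
}

# Welch segment spectra: list of one-sided cross/auto spectra averaged over
# Hann-tapered segments with 50% overlap.
#' @noRd
welch_segments <- function(x, y, seg_len, fs, overlap = 0.5) {
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  nf <- floor(seg_len / 2) + 1L
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  for (s0 in starts) {
    xs <- x[s0:(s0 + seg_len - 1L)]; ys <- y[s0:(s0 + seg_len - 1L)]
    fx <- stats::fft((xs - mean(xs)) * w)[seq_len(nf)]
    fy <- stats::fft((ys - mean(ys)) * w)[seq_len(nf)]
    sxx <- sxx + Mod(fx)^2
    syy <- syy + Mod(fy)^2
    sxy <- sxy + fx * Conj(fy)
  }
  list(freqs = (seq_len(nf) - 1) * fs / seg_len, sxx = sxx, syy = syy,
       sxy = sxy, n_segments = length(starts))
}

#' Magnitude-squared coherence between two traces
#'
#' Welch estimator: Hann-tapered segments with 50% overlap;
#' C(f) = |Sxy|^2 / (Sxx Syy) from the segment-averaged cross- and
#' auto-spectra. Bounded in [0, 1]; for independent signals the estimate has
#' a bias floor of about 1/n_segments.
#'
#' @param x,y equal-length traces at the same sampling rate (resample
#'   upstream if needed).
#' @param segment_s segment duration in seconds.
#' @param fs sampling rate in Hz.
#' @return object of class \code{coherence_spectrum}: \code{freqs_hz},
#'   \code{coherence}, \code{n_segments}.
#' @export
coherence_spectrum <- function(x, y, segment_s, fs) {
  stop_if(length(x) != length(y), "traces must have equal length")
  seg_len <- round(segment_s * fs)
  stop_if(seg_len < 4L, "segment too short")
  step <- max(1L, round(seg_len / 2))
  n_seg <- if (length(x) < seg_len) 0L else
    (length(x) - seg_len) %/% step + 1L
  stop_if(n_seg < 2L,
          "fewer than 2 segments: coherence would be identically 1")
  ws <- welch_segments(x, y, seg_len, fs)
  coh <- Mod(ws$sxy)^2 / (ws$sxx * ws$syy)
  coh[!is.finite(coh)] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  structure(list(freqs_hz = ws$freqs, coherence = coh,
                 n_segments = ws$n_segments),
            class = "coherence_spectrum")
}

#' Cross-frequency power correlation matrix
#'
#' Splits both traces into consecutive windows, computes per-window band
#' power of each signal in 1 Hz bands centered on each requested frequency,
#' and Pearson-correlates the instantaneous powers across windows for every
#' frequency pair. Cells with zero variance in either band are NA.
#'
#' @param x,y equal-length traces at the same sampling rate.
#' @param fs sampling rate, Hz.
#' @param freqs band centers in Hz (default 1:10).
#' @param window_s window duration (default 2 s); the traces must span at
#'   least 20 windows.
#' @return matrix (length(freqs) x length(freqs)): rows index x-frequencies,
#'   columns y-frequencies.
#' @export
crossfreq_power_correlation <- function(x, y, fs, freqs = 1:10, window_s = 2) {
  stop_if(length(x) != length(y), "traces must have equal length")
  wl <- round(window_s * fs)
  nw <- floor(length(x) / wl)
  stop_if(nw < 20L, "traces must span at least 20 windows")
  bandpow <- function(z) {
    out <- matrix(0, nw, length(freqs))
    for (i in seq_len(nw)) {
      seg <- z[((i - 1L) * wl + 1L):(i * wl)]
      f <- stats::fft(seg - mean(seg))[seq_len(floor(wl / 2) + 1L)]
      fr <- (seq_along(f) - 1) * fs / wl
      p <- Mod(f)^2
      for (j in seq_along(freqs)) {
        sel <- fr >= freqs[j] - 0.5 & fr <= freqs[j] + 0.5
        out[i, j] <- sum(p[sel])
      }
    }
    out
  }
  px <- bandpow(x); py <- bandpow(y)
  m <- matrix(NA_real_, length(freqs), length(freqs),
              dimnames = list(paste0(freqs, "Hz"), paste0(freqs, "Hz")))
  for (a in seq_along(freqs)) {
    for (b in seq_along(freqs)) {
      if (stats::sd(px[, a]) > 0 && stats::sd(py[, b]) > 0) {
        m[a, b] <- stats::cor(px[, a], py[, b])
      }
    }
  }
  m
}

#' Fit a linear spatiotemporal filter predicting MUA from the movie
#'
#' Ridge-regularized regression from time-lagged compressed components (the
#' rows of V) to the MUA rate, with the penalty chosen on a log-spaced grid
#' by blocked cross-validation (contiguous folds, so temporally correlated
#' samples do not leak across folds). The fitted k x n_lags coefficient
#' matrix is factorized (rank 1) into a pixel-space spatial weight map and a
#' temporal kernel.
#'
#' @param store an \code{svd_store}.
#' @param mua a \code{mua_trace} on (approximately) the store's frame grid.
#' @param lags_s lag range (min, max) in seconds; positive lags mean the
#'   movie precedes the spikes.
#' @param lambda_grid ridge penalties to search (default 10^seq(-2, 4)).
#' @param n_folds blocked CV folds (default 5).
#' @return list: \code{weight_map} (rows x cols spatial map),
#'   \code{temporal_kernel}, \code{lags_s}, \code{cv_r} (held-out
#'   prediction correlation at the chosen penalty), \code{lambda},
#'   \code{coef} (k x n_lags).
#' @export
fit_spike_prediction_filter <- function(store, mua, lags_s = c(-0.2, 0.6),
                                        lambda_grid = 10^seq(-2, 4, by = 1),
                                        n_folds = 5L) {
  fs <- store_fs(store)
  y_all <- stats::approx(mua$timestamps_s, mua$rate, xout = store$timestamps,
                         rule = 2)$y
  lag_idx <- seq(round(lags_s[1] * fs), round(lags_s[2] * fs))
  k <- nrow(store$V)
  t_ok <- (1 + max(0, max(lag_idx))):(ncol(store$V) + min(0, min(lag_idx)))
  stop_if(length(t_ok) < 10L * length(lag_idx), "insufficient overlapping time support")
  X <- matrix(0, length(t_ok), k * length(lag_idx))
  for (li in seq_along(lag_idx)) {
    X[, ((li - 1L) * k + 1L):(li * k)] <- t(store$V[, t_ok - lag_idx[li], drop = FALSE])
  }
  y <- y_all[t_ok]
  X <- scale(X, scale = FALSE); y_c <- y - mean(y)
  folds <- cut(seq_along(y), n_folds, labels = FALSE)
  cv_r <- sapply(lambda_grid, function(lam) {
    preds <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      XtX <- crossprod(X[tr, , drop = FALSE])
      b <- solve(XtX + lam * diag(ncol(X)),
                 crossprod(X[tr, , drop = FALSE], y_c[tr]))
      preds[!tr] <- X[!tr, , drop = FALSE] %*% b
    }
    if (stats::sd(preds) == 0) 0 else stats::cor(preds, y_c)
  })
  best <- which.max(cv_r)
  b <- solve(crossprod(X) + lambda_grid[best] * diag(ncol(X)), crossprod(X, y_c))
  B <- matrix(b, k, length(lag_idx))
  dec <- svd(B, nu = 1, nv = 1)
  spat <- dec$u[, 1] * dec$d[1]
  kern <- dec$v[, 1]
  if (kern[which.max(abs(kern))] < 0) { kern <- -kern; spat <- -spat }
  wm <- drop(store$U %*% spat)
  list(weight_map = matrix(wm, store$pixel_shape[1], store$pixel_shape[2],
                           byrow = TRUE),
       temporal_kernel = kern, lags_s = lag_idx / fs,
       cv_r = cv_r[best], lambda = lambda_grid[best], coef = B,
       cv_path = data.frame(lambda = lambda_grid, cv_r = cv_r))
}
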