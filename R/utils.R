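# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Derive independent child seeds from one root seed
#'
#' All randomness in the package flows from a single integer seed through
#' named child streams, so each component of a synthetic session can be
#' regenerated independently and deterministically.
#'
#' @param seed integer root seed.
#' @param streams character vector of stream names.
#' @return named integer vector of child seeds (all < 2^31).
#' @keywords internal
child_seeds <- function(seed, streams) {
  stop_if(!is.numeric(seed) || length(seed) != 1L || !is.finite(seed),
          "seed must be a single finite integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  out <- sample.int(.Machine$integer.max, length(streams))
  names(out) <- streams
  out
}

# Zero-phase FFT-domain filter: keeps Fourier coefficients with
# low <= |f| <= high and zeroes the rest. Operates on the rows of a matrix
# (or on a vector). Exact zero phase; brick-wall edges.
#' @noRd
fft_bandpass <- function(x, fs, low = 0, high = Inf) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  f <- abs(seq(0, n - 1) * fs / n)
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  keep <- f >= low & f <= high
  X <- t(stats::mvfft(t(x)))
  X[, !keep] <- 0
  out <- Re(t(stats::mvfft(t(X), inverse = TRUE))) / n
  if (vec) drop(out) else out
}

# Remove per-row linear trend (least squares line over sample index).
#' @noRd
detrend_linear <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  tt <- seq_len(n) - (n + 1) / 2            # centered regressor
  denom <- sum(tt^2)
  slope <- (x %*% tt) / denom
  mean_x <- rowMeans(x)
  out <- x - outer(drop(mean_x), rep(1, n)) - outer(drop(slope), tt)
  if (vec) drop(out) else out
}

# Counts of events in half-open bins [edges[i], edges[i+1]).
#' @noRd
bin_counts_edges <- function(x, edges) {
  x <- x[x >= edges[1] & x < edges[length(edges)]]
  tabulate(findInterval(x, edges), nbins = length(edges) - 1L)
}

# Map a half-open time window [start, end) in seconds to frame indices.
#' @noRd
frames_in_window <- function(timestamps, window) {
  stop_if(length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2],
          "window must be a finite (start, end) pair with start < end")
  which(timestamps >= window[1] & timestamps < window[2])
}
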