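#' SVD-compressed widefield movie store
#'
#' A widefield movie reshaped to a pixels x time matrix S is held as a
#' truncated singular value decomposition S = A Lambda B'. The store keeps
#' the spatial components \code{U} (the first k columns of A) and the
#' singular-value-scaled temporal components \code{V} (the first k rows of
#' Lambda B'), so the fluorescence of pixel n is the plain matrix product
#' f_n(t) = U[n, ] \%*\% V. Storing V pre-scaled keeps that reconstruction
#' literal; the singular values are also kept separately.
#'
#' Coordinates are 0-based (row, col) with row-major flattening to the pixel
#' index; all time windows are half-open [start, end) in seconds.
#'
#' @param U pixels x k matrix with orthonormal columns (spatial components).
#' @param V k x time matrix of singular-value-scaled temporal components.
#' @param sv length-k nonincreasing vector of singular values.
#' @param timestamps frame times in seconds, strictly increasing.
#' @param pixel_shape integer (rows, cols); prod(pixel_shape) == nrow(U).
#' @param channel one of "calcium", "hemo", "corrected", "uncorrected".
#' @return an object of class \code{svd_store}.
#' @export
svd_store <- function(U, V, sv, timestamps, pixel_shape,
                      channel = c("calcium", "hemo", "corrected", "uncorrected")) {
  channel <- match.arg(channel)
  U <- as.matrix(U); V <- as.matrix(V)
  stop_if(ncol(U) != nrow(V), "U and V have incompatible ranks")
  stop_if(length(sv) != ncol(U), "singular value count must equal rank")
  stop_if(any(diff(sv) > 1e-8 * max(sv, 1)), "singular values must be nonincreasing")
  stop_if(any(sv < -1e-12), "singular values must be nonnegative")
  stop_if(length(timestamps) != ncol(V), "one timestamp per frame required")
  stop_if(any(diff(timestamps) <= 0), "timestamps must be strictly increasing")
  stop_if(prod(pixel_shape) != nrow(U), "pixel_shape inconsistent with nrow(U)")
  structure(list(U = U, V = V, sv = as.numeric(sv), k = ncol(U),
                 timestamps = as.numeric(timestamps),
                 pixel_shape = as.integer(pixel_shape), channel = channel),
            class = "svd_store")
}

#' @export
print.svd_store <- function(x, ...) {
  cat(sprintf("svd_store [%s]: %d x %d pixels, %d frames, rank %d, fs ~ %.2f Hz\n",
              x$channel, x$pixel_shape[1], x$pixel_shape[2],
              ncol(x$V), x$k, store_fs(x)))
  invisible(x)
}

#' Median sampling rate of a store (Hz)
#' @param store an \code{svd_store}.
#' @export
store_fs <- function(store) 1 / stats::median(diff(store$timestamps))

# 0-based (row, col) -> 1-based row-major pixel index
#' @noRd
pixel_index <- function(store, row, col) {
  nr <- store$pixel_shape[1]; nc <- store$pixel_shape[2]
  stop_if(any(row < 0 | row >= nr | col < 0 | col >= nc),
          "pixel coordinate outside the ", nr, " x ", nc, " grid")
  as.integer(row * nc + col + 1L)
}

#' Compress a pixels x time movie by truncated SVD
#'
#' Physiological widefield dynamics are captured by the leading singular
#' values (500 suffices for full-size recordings); the remainder is noise.
#' The sign ambiguity of each component pair is fixed by forcing the
#' largest-magnitude entry of every spatial component to be positive.
#'
#' @param frames pixels x time numeric matrix (row-major flattened frames).
#' @param timestamps frame times in seconds.
#' @param k truncation rank (default 500, capped at the matrix rank).
#' @param pixel_shape (rows, cols) of the imaging grid; defaults to a square
#'   grid when \code{nrow(frames)} is a perfect square.
#' @param channel channel tag for the resulting store.
#' @return an \code{svd_store} holding the top-k decomposition. The squared
#'   Frobenius reconstruction error equals the sum of squared discarded
#'   singular values (Eckart-Young).
#' @export
compress_movie <- function(frames, timestamps, k = 500L, pixel_shape = NULL,
                           channel = "calcium") {
  frames <- as.matrix(frames)
  stop_if(!all(is.finite(frames)), "movie contains non-finite values")
  stop_if(k <= 0, "k must be positive")
  if (is.null(pixel_shape)) {
    side <- sqrt(nrow(frames))
    stop_if(side != floor(side), "pixel_shape required for non-square grids")
    pixel_shape <- c(side, side)
  }
  k <- min(as.integer(k), nrow(frames), ncol(frames))
  if (k < nrow(frames) && ncol(frames) > 2L * nrow(frames)) {
    # truncated decomposition of a wide matrix: eigen-decompose the p x p
    # Gram matrix (much faster than a full SVD; V = U'S is Lambda B' exactly)
    e <- eigen(tcrossprod(frames), symmetric = TRUE)
    U <- e$vectors[, seq_len(k), drop = FALSE]
    sv <- sqrt(pmax(e$values[seq_len(k)], 0))
    V <- t(U) %*% frames
  } else {
    dec <- svd(frames, nu = k, nv = k)
    U <- dec$u
    sv <- dec$d[seq_len(k)]
    V <- t(dec$v) * sv                   # rows scaled: V = Lambda B'
  }
  for (j in seq_len(k)) {                # sign convention
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) { U[, j] <- -U[, j]; V[j, ] <- -V[j, ] }
  }
  svd_store(U, V, sv, timestamps, pixel_shape, channel)
}

#' Reconstruct selected pixels over a time slice
#'
#' Lazily evaluates U[n, ] \%*\% V for the requested pixels and frames; the
#' full movie is never materialized.
#'
#' @param store an \code{svd_store}.
#' @param pixel_indices 1-based row-major pixel indices (possibly empty), or
#'   an n x 2 matrix of 0-based (row, col) coordinates.
#' @param time_slice half-open (start, end) window in seconds, or NULL for
#'   the whole recording.
#' @return pixels x frames matrix (0 x 0 for an empty index set).
#' @export
reconstruct_pixels <- function(store, pixel_indices, time_slice = NULL) {
  if (is.matrix(pixel_indices)) {
    pixel_indices <- pixel_index(store, pixel_indices[, 1], pixel_indices[, 2])
  }
  if (length(pixel_indices) == 0L) return(matrix(0, 0, 0))
  stop_if(any(pixel_indices < 1L | pixel_indices > nrow(store$U)),
          "pixel index out of range")
  cols <- if (is.null(time_slice)) seq_len(ncol(store$V)) else
    frames_in_window(store$timestamps, time_slice)
  store$U[pixel_indices, , drop = FALSE] %*% store$V[, cols, drop = FALSE]
}

#' Extract the fluorescence trace of one pixel
#'
#' Returns the dot product of the pixel's spatial weights with the temporal
#' components. Note that because of the spatial smoothing inherent in a
#' truncated SVD this trace effectively averages a slightly larger region
#' than one pixel.
#'
#' @param store an \code{svd_store}.
#' @param row,col 0-based pixel coordinates.
#' @return list with \code{timestamps} and \code{trace}.
#' @export
extract_pixel_trace <- function(store, row, col) {
  idx <- pixel_index(store, row, col)
  list(timestamps = store$timestamps,
       trace = drop(store$U[idx, , drop = FALSE] %*% store$V))
}
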