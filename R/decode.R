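# Population decoding of contralateral stimulus presence.

#' Build the trial x unit spike-count matrix
#'
#' Counts each unit's spikes in a post-stimulus window (default 50-150 ms,
#' the optimal 100 ms bin) for every trial, labels trials by contralateral
#' (right-side) stimulus presence, and carries the per-trial condition tags
#' used for the split comparisons.
#'
#' @param spikes a \code{spike_data}.
#' @param trials classified trial table.
#' @param window_ms (start, end) in ms after stimulus onset.
#' @return object of class \code{spike_count_matrix}: integer matrix
#'   \code{counts} (trials x units), logical \code{label} (stimulus
#'   present), \code{contrast} (the contralateral contrast), \code{trials}
#'   (the trial rows used), \code{window_ms}.
#' @export
spike_count_matrix <- function(spikes, trials, window_ms = c(50, 150)) {
  units <- sort(unique(spikes$cluster_ids))
  n <- nrow(trials)
  counts <- matrix(0L, n, length(units),
                   dimnames = list(NULL, paste0("u", units)))
  for (i in seq_len(n)) {
    lo <- trials$stim_onset_s[i] + window_ms[1] / 1000
    hi <- trials$stim_onset_s[i] + window_ms[2] / 1000
    sel <- spikes$spike_times_s >= lo & spikes$spike_times_s < hi
    if (any(sel)) {
      tb <- table(factor(spikes$cluster_ids[sel], levels = units))
      counts[i, ] <- as.integer(tb)
    }
  }
  structure(list(counts = counts, label = trials$contrast_right > 0,
                 contrast = trials$contrast_right,
                 trials = trials, window_ms = window_ms),
            class = "spike_count_matrix")
}

# Subset a spike_count_matrix by a logical/integer index
#' @noRd
scm_subset <- function(m, idx) {
  structure(list(counts = m$counts[idx, , drop = FALSE],
                 label = m$label[idx], contrast = m$contrast[idx],
                 trials = m$trials[idx, , drop = FALSE],
                 window_ms = m$window_ms),
            class = "spike_count_matrix")
}

#' Equalize trial counts between two decoder conditions
#'
#' Within each contrast level present in both conditions, randomly
#' subsamples (seeded) the larger condition down to the smaller's trial
#' count, so both decoders see equal training data per contrast; for
#' example, 26 Choice versus 18 Miss trials at one contrast yields 18
#' retained Choice trials. Contrast levels with zero trials in either
#' condition are dropped with a message. Original trial order is preserved.
#'
#' @param matrix a \code{spike_count_matrix}.
#' @param condition_a,condition_b logical vectors over its trials (or
#'   functions of the trial table) defining the two conditions.
#' @param seed integer seed for the subsampling.
#' @return list of two \code{spike_count_matrix} objects (\code{a},
#'   \code{b}) with identical per-contrast trial counts.
#' @export
equalize_trial_counts <- function(matrix, condition_a, condition_b, seed = 1L) {
  in_a <- if (is.function(condition_a)) condition_a(matrix$trials) else condition_a
  in_b <- if (is.function(condition_b)) condition_b(matrix$trials) else condition_b
  stop_if(!any(in_a, na.rm = TRUE) || !any(in_b, na.rm = TRUE),
          "both conditions must contain trials")
  in_a[is.na(in_a)] <- FALSE; in_b[is.na(in_b)] <- FALSE
  set.seed(as.integer(seed))
  keep_a <- logical(length(in_a)); keep_b <- logical(length(in_b))
  any_common <- FALSE
  for (cv in sort(unique(matrix$contrast))) {
    ia <- which(in_a & matrix$contrast == cv)
    ib <- which(in_b & matrix$contrast == cv)
    if (length(ia) == 0L || length(ib) == 0L) {
      if (length(ia) + length(ib) > 0L) {
        message("contrast ", cv, " dropped: present in only one condition")
      }
      next
    }
    any_common <- TRUE
    m <- min(length(ia), length(ib))
    keep_a[sort(sample(ia, m))] <- TRUE
    keep_b[sort(sample(ib, m))] <- TRUE
  }
  stop_if(!any_common, "no contrast level has trials in both conditions")
  list(a = scm_subset(matrix, which(keep_a)),
       b = scm_subset(matrix, which(keep_b)))
}

# Stratified fold assignment: labels balanced across folds, seeded.
#' @noRd
stratified_folds <- function(label, n_folds) {
  fold <- integer(length(label))
  for (lv in unique(label)) {
    idx <- sample(which(label == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated decoding of stimulus presence
#'
#' L2-penalized (ridge) logistic regression predicting contralateral
#' stimulus presence from the population spike-count vector, scored by
#' 5-fold stratified cross-validation. The penalty is chosen within each
#' training fold by inner cross-validation over a fixed log-spaced grid
#' (nested CV, so the reported score is unbiased). Folds are seeded.
#'
#' @param matrix a \code{spike_count_matrix} (>= 10 trials, both labels).
#' @param seed integer seed for fold assignment.
#' @param n_folds outer folds (default 5).
#' @return list: \code{accuracy}, \code{log_loss}, \code{n},
#'   \code{predictions} (per-trial held-out probabilities).
#' @export
decode_stimulus <- function(matrix, seed = 1L, n_folds = 5L) {
  y <- matrix$label
  X <- matrix$counts
  stop_if(length(y) < 10L, "need at least 10 trials")
  stop_if(length(unique(y)) < 2L, "both labels must be present")
  set.seed(as.integer(seed))
  fold <- stratified_folds(y, n_folds)
  lambda_grid <- 10^seq(2, -4, length.out = 40)
  prob <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    inner <- stratified_folds(y[tr], min(5L, min(table(y[tr]))))
    cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = 0, lambda = lambda_grid, foldid = inner,
                            standardize = TRUE)
    prob[!tr] <- stats::predict(cv, X[!tr, , drop = FALSE],
                                s = "lambda.min", type = "response")
  }
  eps <- 1e-12
  list(accuracy = mean((prob > 0.5) == y),
       log_loss = -mean(y * log(pmax(prob, eps)) +
                          (1 - y) * log(pmax(1 - prob, eps))),
       n = length(y), predictions = prob)
}

#' Split trials at the median of a state measure
#'
#' Trials strictly below the median go to the low set, strictly above to
#' the high set; trials exactly at the median are excluded (keeping "below
#' and above the median" literal), with counts reported.
#'
#' @param values numeric state measure per trial (e.g. a
#'   \code{band_power_table} power column, or \code{fano_result$fano}).
#' @return list: \code{low}, \code{high} (integer indices), \code{n_ties}
#'   (excluded), \code{median}.
#' @export
median_state_split <- function(values) {
  ok <- which(is.finite(values))
  stop_if(length(ok) < 2L, "need at least 2 trials with finite values")
  med <- stats::median(values[ok])
  low <- ok[values[ok] < med]
  high <- ok[values[ok] > med]
  stop_if(length(low) == 0L && length(high) == 0L,
          "all values identical: median split is degenerate")
  list(low = low, high = high, n_ties = length(ok) - length(low) - length(high),
       median = med)
}
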