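# Cross-file fixtures: the worked percentile composition and a
# composable spike-count matrix.

# A single-session band-power table whose first percentile bin reproduces a
# given composition. Powers are 1..n so bin edges are deterministic.
composed_table <- function() {
  outc <- c(rep("CorrectChoice", 28), rep("IncorrectChoice", 7),  # non-equal
            "CorrectChoice",                                      # equal contrast
            rep("Miss", 4),
            rep("CorrectReject", 6), rep("FalseAlarm", 4))        # zero contrast
  cl <- c(rep(0, 28), rep(0.5, 7), 0.5, rep(0, 4), rep(0, 10))
  cr <- c(rep(0.5, 28), rep(0, 7), 0.5, rep(0.5, 4), rep(0, 10))
  n_rest <- 200
  df <- data.frame(
    outcome = c(outc, rep(c("CorrectChoice", "Miss"), length.out = n_rest)),
    contrast_left = c(cl, rep(0, n_rest)),
    contrast_right = c(cr, rep(1, n_rest)),
    session_id = "s1",
    power_VIS = as.numeric(1:250))
  class(df) <- c("band_power_table", "data.frame")
  df
}

# Spike-count matrix with controllable per-contrast composition
fake_scm <- function(n_per_cell, seed = 61, n_units = 12, sep = 0) {
  set.seed(seed)
  trials <- do.call(rbind, lapply(seq_len(nrow(n_per_cell)), function(i) {
    data.frame(outcome = n_per_cell$outcome[i],
               contrast_right = n_per_cell$contrast[i])[rep(1, n_per_cell$n[i]), ]
  }))
  rownames(trials) <- NULL
  lab <- trials$contrast_right > 0
  counts <- matrix(rpois(nrow(trials) * n_units, 3), nrow(trials), n_units)
  counts[lab, ] <- counts[lab, ] + matrix(rpois(sum(lab) * n_units, sep),
                                          sum(lab), n_units)
  structure(list(counts = counts, label = lab,
                 contrast = trials$contrast_right, trials = trials,
                 window_ms = c(50, 150)),
            class = "spike_count_matrix")
}

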