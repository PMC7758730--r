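# Trial classification and state-vs-behavior statistics.

#' Classify trials from raw events
#'
#' Assigns each trial one of five outcomes. With a stimulus present, a wheel
#' response inside the response window is a Choice (Correct if in the
#' required direction, Incorrect otherwise; equal-contrast trials are
#' rewarded at random, so correctness follows the recorded reward); no
#' response is a Miss. With zero contrast on both sides, withholding through
#' the response window is a Correct Reject and turning is a False Alarm.
#' Trials whose recorded response falls outside the response window are
#' contradictory: they are flagged invalid (outcome NA) and counted.
#'
#' @param events data.frame with columns contrast_left, contrast_right,
#'   response_s (NA when no response), response_direction (-1/0/1), gocue_s,
#'   response_window_end_s, and rewarded (used only for equal-contrast
#'   trials).
#' @return the input with columns \code{outcome} and \code{valid};
#'   attribute \code{n_invalid} counts excluded contradictory trials.
#' @export
classify_trials <- function(events) {
  n <- nrow(events)
  has_resp <- !is.na(events$response_s)
  invalid <- has_resp & (events$response_s <= events$gocue_s |
                           events$response_s > events$response_window_end_s)
  outcome <- rep(NA_character_, n)
  zero <- events$contrast_left == 0 & events$contrast_right == 0
  req <- sign(events$contrast_right - events$contrast_left)
  for (j in seq_len(n)) {
    if (invalid[j]) next
    if (zero[j]) {
      outcome[j] <- if (has_resp[j]) "FalseAlarm" else "CorrectReject"
    } else if (!has_resp[j]) {
      outcome[j] <- "Miss"
    } else if (req[j] == 0) {
      outcome[j] <- if (isTRUE(events$rewarded[j])) "CorrectChoice" else "IncorrectChoice"
    } else {
      outcome[j] <- if (events$response_direction[j] == req[j])
        "CorrectChoice" else "IncorrectChoice"
    }
  }
  events$outcome <- outcome
  events$valid <- !invalid
  if (any(invalid)) {
    message(sum(invalid), " trial(s) with a response outside the response window excluded as invalid")
  }
  attr(events, "n_invalid") <- sum(invalid)
  events
}

#' Extract valid quiescent windows
#'
#' Returns the half-open pre-stimulus quiescent window [quiescent_start,
#' quiescent_end) of every trial whose quiescent duration is at least
#' \code{min_duration_s} (strictly shorter windows are excluded; exactly
#' 0.7 s is included). The exclusion count is reported as an attribute.
#'
#' @param trials trial table with quiescent_start_s / quiescent_end_s.
#' @param min_duration_s minimum quiescent duration (default 0.7).
#' @param lag analyse the quiescent window of the trial \code{lag} trials
#'   after each row (default 0; use 1 for post-outcome analyses of the
#'   following trial's quiescence).
#' @return data.frame with columns trial, start_s, end_s; attributes
#'   \code{n_included} and \code{n_excluded}.
#' @export
extract_quiescent_windows <- function(trials, min_duration_s = 0.7, lag = 0L) {
  if (nrow(trials) == 0L) {
    out <- data.frame(trial = integer(), start_s = numeric(), end_s = numeric())
    attr(out, "n_included") <- 0L; attr(out, "n_excluded") <- 0L
    return(out)
  }
  idx <- seq_len(nrow(trials)) + as.integer(lag)
  ok_lag <- idx >= 1L & idx <= nrow(trials)
  dur <- rep(NA_real_, nrow(trials))
  dur[ok_lag] <- trials$quiescent_end_s[idx[ok_lag]] -
    trials$quiescent_start_s[idx[ok_lag]]
  # strict less-than exclusion, guarded against FP jitter so that a duration
  # of exactly the minimum is included
  keep <- ok_lag & dur >= min_duration_s - 1e-9
  out <- data.frame(trial = which(keep),
                    start_s = trials$quiescent_start_s[idx[keep]],
                    end_s = trials$quiescent_end_s[idx[keep]])
  attr(out, "n_included") <- sum(keep)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Build the trial x ROI band-power table
#'
#' Computes, per included trial (quiescent duration >= \code{min_quiescent_s},
#' invalid trials dropped), the quiescent-window band power at each ROI
#' pixel, both raw (a.u.^2, columns \code{power_<ROI>}) and in dB relative
#' to the session mean (columns \code{db_<ROI>}, the cross-session
#' comparable quantity), joined to outcome, contrasts, reaction time
#' (go cue to response) and, if supplied, quiescent-window pupil means.
#'
#' @param store corrected \code{svd_store} of the session.
#' @param trials classified trial table.
#' @param rois a \code{roi_set} (named list of 0-based (row, col) pairs).
#' @param band_hz analysis band (default c(3, 6)).
#' @param min_quiescent_s exclusion threshold (default 0.7).
#' @param pupil optional \code{pupil_trace}.
#' @return data.frame of class \code{band_power_table}; attributes
#'   \code{rois}, \code{band_hz}, \code{provenance} (n_raw, n_included,
#'   n_excluded, n_invalid).
#' @export
band_power_table <- function(store, trials, rois, band_hz = c(3, 6),
                             min_quiescent_s = 0.7, pupil = NULL) {
  n_invalid <- 0L
  if ("valid" %in% names(trials)) {
    n_invalid <- sum(!trials$valid)
    trials_v <- trials[trials$valid, , drop = FALSE]
  } else trials_v <- trials
  qw <- extract_quiescent_windows(trials_v, min_quiescent_s)
  stop_if(nrow(qw) == 0L, "no trial passes the quiescent-duration criterion")
  windows <- lapply(seq_len(nrow(qw)), function(i) c(qw$start_s[i], qw$end_s[i]))
  tab <- trials_v[qw$trial, , drop = FALSE]
  tab$reaction_time_s <- tab$response_s - tab$gocue_s
  for (nm in names(rois)) {
    p <- roi_band_power(store, rois[[nm]], windows, band_hz)
    tab[[paste0("power_", nm)]] <- p
    db <- 10 * log10(p)
    tab[[paste0("db_", nm)]] <- db - mean(db[is.finite(db)])
  }
  if (!is.null(pupil)) {
    tab$pupil_mean <- vapply(windows, function(w) {
      i <- frames_in_window(pupil$timestamps_s, w)
      mean(pupil$diameter[i])
    }, numeric(1))
    tab$pupil_derivative_mean <- vapply(windows, function(w) {
      i <- frames_in_window(pupil$timestamps_s, w)
      mean(pupil$derivative[i])
    }, numeric(1))
  }
  attr(tab, "rois") <- rois
  attr(tab, "band_hz") <- band_hz
  attr(tab, "provenance") <- list(n_raw = nrow(trials),
                                  n_included = nrow(qw),
                                  n_excluded = attr(qw, "n_excluded"),
                                  n_invalid = n_invalid)
  class(tab) <- c("band_power_table", "data.frame")
  tab
}

# Percentile bin (1..5) of each value, edges at the 20/40/60/80% points of
# the distribution (linear interpolation between order statistics, the
# convention of the original analysis environment's prctile; R type 5).
# Membership: [0,20) -> 1, ..., [80,100] -> 5 (half-open-left).
#' @noRd
percentile_bins <- function(x) {
  edges <- stats::quantile(x, c(0.2, 0.4, 0.6, 0.8), type = 5, names = FALSE)
  if (length(unique(x)) == 1L) {
    warning("all powers identical: single-bin degenerate case", call. = FALSE)
    return(list(bin = rep(1L, length(x)), edges = edges, degenerate = TRUE))
  }
  list(bin = findInterval(x, edges, left.open = FALSE) + 1L,
       edges = edges, degenerate = FALSE)
}

# The worked per-bin arithmetic: rates (%) from category counts.
#' @noRd
rates_from_counts <- function(cnt) {
  pct <- function(a, b) ifelse(b > 0, 100 * a / b, NA_real_)
  data.frame(pct_choice = pct(cnt$N_choice, cnt$N_contrast),
             pct_miss = pct(cnt$N_miss, cnt$N_contrast),
             pct_correct = pct(cnt$N_correct, cnt$N_nonequalContrast),
             pct_incorrect = pct(cnt$N_incorrect, cnt$N_nonequalContrast),
             pct_reject = pct(cnt$N_reject, cnt$N_zero),
             pct_falsealarm = pct(cnt$N_falsealarm, cnt$N_zero))
}

#' @noRd
bin_counts <- function(tab, bin, b) {
  in_bin <- bin == b
  out <- tab$outcome[in_bin]
  contrast <- (tab$contrast_left[in_bin] > 0 | tab$contrast_right[in_bin] > 0)
  equal <- tab$contrast_left[in_bin] == tab$contrast_right[in_bin]
  choice <- out %in% c("CorrectChoice", "IncorrectChoice")
  data.frame(bin = b,
             N_trials = sum(in_bin),
             N_contrast = sum(contrast),
             N_zero = sum(!contrast),
             N_choice = sum(contrast & choice),
             N_miss = sum(contrast & out == "Miss"),
             N_nonequalContrast = sum(contrast & choice & !equal),
             N_correct = sum(contrast & choice & !equal & out == "CorrectChoice"),
             N_incorrect = sum(contrast & choice & !equal & out == "IncorrectChoice"),
             N_reject = sum(!contrast & out == "CorrectReject"),
             N_falsealarm = sum(!contrast & out == "FalseAlarm"))
}

#' Behavioral rates by power percentile
#'
#' Bins trials into five percentile classes of ROI band power (edges at the
#' 20/40/60/80% points, computed per session), then computes per bin the
#' worked arithmetic: %Choice and %Miss among stimulus trials, %Correct and
#' %Incorrect among non-equal-contrast Choice trials (equal-contrast trials
#' are rewarded at random and excluded there), %Correct Reject and %False
#' Alarm among zero-contrast trials. With several sessions, counts are
#' binned per session and rates averaged across sessions.
#'
#' @param table a \code{band_power_table}.
#' @param roi ROI name (a \code{power_<roi>} column must exist).
#' @return object of class \code{percentile_rates}: data.frame \code{rates}
#'   (one row per bin: counts summed over sessions, rates averaged),
#'   \code{edges} (per session), \code{roi}.
#' @export
percentile_rates <- function(table, roi) {
  col <- paste0("power_", roi)
  stop_if(!col %in% names(table), "no power column for ROI ", roi)
  x <- table[[col]]
  ok <- is.finite(x)
  stop_if(sum(ok) < 5L, "need at least 5 trials with finite power")
  tab <- table[ok, , drop = FALSE]
  x <- x[ok]
  sessions <- unique(tab$session_id)
  edges <- list(); per_sess <- list()
  for (s in sessions) {
    sel <- tab$session_id == s
    pb <- percentile_bins(x[sel])
    edges[[s]] <- pb$edges
    cnt <- do.call(rbind, lapply(1:5, function(b)
      bin_counts(tab[sel, , drop = FALSE], pb$bin, b)))
    per_sess[[s]] <- cbind(cnt, rates_from_counts(cnt))
  }
  counts_cols <- c("N_trials", "N_contrast", "N_zero", "N_choice", "N_miss",
                   "N_nonequalContrast", "N_correct", "N_incorrect",
                   "N_reject", "N_falsealarm")
  rate_cols <- c("pct_choice", "pct_miss", "pct_correct", "pct_incorrect",
                 "pct_reject", "pct_falsealarm")
  rates <- data.frame(bin = 1:5)
  for (cc in counts_cols) {
    rates[[cc]] <- Reduce(`+`, lapply(per_sess, `[[`, cc))
  }
  for (cc in rate_cols) {
    m <- sapply(per_sess, `[[`, cc)
    m <- matrix(m, nrow = 5)
    rates[[cc]] <- rowMeans(m, na.rm = TRUE)
  }
  structure(list(rates = rates, edges = edges, roi = roi),
            class = "percentile_rates")
}

#' @export
print.percentile_rates <- function(x, ...) {
  cat("Behavioral rates by", x$roi, "power percentile bin:\n")
  print(x$rates, digits = 3)
  invisible(x)
}

#' Correlation between power and reaction-time residuals
#'
#' Reaction time (go-cue onset to response) varies between stimuli, so the
#' per-contrast-condition mean is subtracted first; the residuals are then
#' Pearson-correlated with ROI band power over Choice trials.
#'
#' @param table a \code{band_power_table}.
#' @param roi ROI name.
#' @return list: \code{r}, \code{p_value}, \code{n}, \code{undefined}
#'   (TRUE, with r = NA and a warning, when residuals have zero variance).
#' @export
rt_power_correlation <- function(table, roi) {
  col <- paste0("power_", roi)
  sel <- table$outcome %in% c("CorrectChoice", "IncorrectChoice") &
    is.finite(table$reaction_time_s) & is.finite(table[[col]])
  stop_if(sum(sel) < 3L, "need at least 3 Choice trials with reaction times")
  tab <- table[sel, , drop = FALSE]
  cond <- interaction(tab$contrast_left, tab$contrast_right, drop = TRUE)
  resid <- tab$reaction_time_s - stats::ave(tab$reaction_time_s, cond)
  if (stats::sd(resid) == 0 || stats::sd(tab[[col]]) == 0) {
    warning("zero-variance residuals: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p_value = NA_real_, n = nrow(tab),
                undefined = TRUE))
  }
  ct <- stats::cor.test(resid, tab[[col]])
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(tab),
       undefined = FALSE)
}

#' Parallel-lines ANCOVA of power on a pupil covariate
#'
#' Fits power ~ covariate + condition by least squares: one shared slope,
#' one intercept per behavioral condition (parallel lines by construction).
#' The intercept difference is the condition effect at matched pupil, with
#' its p-value.
#'
#' @param table a \code{band_power_table} built with a pupil trace.
#' @param roi ROI name (the dB column is used).
#' @param covariate "diameter" or "derivative".
#' @param conditions length-2 grouping: "Choice" pools Correct and Incorrect
#'   choices; any outcome name is used as is.
#' @return object of class \code{ancova_result}: \code{common_slope},
#'   \code{intercepts}, \code{intercept_difference} (second minus first
#'   condition), \code{p_value}, \code{n}.
#' @export
pupil_ancova <- function(table, roi, covariate = c("diameter", "derivative"),
                         conditions = c("Choice", "Miss")) {
  covariate <- match.arg(covariate)
  ccol <- if (covariate == "diameter") "pupil_mean" else "pupil_derivative_mean"
  stop_if(!ccol %in% names(table), "table was built without a pupil trace")
  cond <- outcome_to_condition(table$outcome, conditions)
  sel <- !is.na(cond) & is.finite(table[[ccol]])
  tab <- table[sel, , drop = FALSE]
  cond <- factor(cond[sel], levels = conditions)
  stop_if(any(tabulate(cond, 2L) < 3L),
          "both conditions need at least 3 trials with a finite covariate")
  y <- tab[[paste0("db_", roi)]]
  fit <- stats::lm(y ~ x + cond, data = data.frame(y = y, x = tab[[ccol]], cond = cond))
  sm <- summary(fit)$coefficients
  ic <- c(stats::coef(fit)[1], stats::coef(fit)[1] + stats::coef(fit)[3])
  names(ic) <- conditions
  structure(list(common_slope = unname(stats::coef(fit)[2]),
                 intercepts = ic,
                 intercept_difference = unname(stats::coef(fit)[3]),
                 p_value = sm[3, 4],
                 n = as.integer(table(cond))),
            class = "ancova_result")
}

# Map outcomes onto a condition pair; NA for outcomes outside the pair.
#' @noRd
outcome_to_condition <- function(outcome, pair) {
  grouped <- ifelse(outcome %in% c("CorrectChoice", "IncorrectChoice"),
                    "Choice", outcome)
  out <- ifelse(grouped %in% pair, grouped, NA_character_)
  if (all(is.na(out))) {    # pair may name raw outcomes (e.g. CorrectChoice)
    out <- ifelse(outcome %in% pair, outcome, NA_character_)
  }
  out
}

#' Nested mixed-effects test of a condition effect on band power
#'
#' Fits, by maximum likelihood, power ~ cond + area with area-specific
#' random effects nested in genotype, subject within genotype, and session
#' within subject (power ~ cond + area + (area | genotype) +
#' (area | subject:genotype) + (area | session:subject:genotype)), or the
#' interaction model cond * area when requested. The p-value for the
#' condition (or interaction) term is a likelihood-ratio test. Sessions
#' with fewer than \code{min_trials} trials in either compared condition
#' are excluded. Random terms whose grouping factor has a single level are
#' dropped (a single-session table collapses to ordinary least squares).
#'
#' @param table a \code{band_power_table} (its \code{db_<ROI>} columns are
#'   stacked into long format), or an already-long data.frame with columns
#'   power_db, cond, area, genotype_id, subject_id, session_id.
#' @param condition_pair the two condition labels to compare.
#' @param with_interaction also test the cond x area interaction.
#' @param min_trials per-session minimum trials per condition (default 10).
#' @return list: \code{estimates} (term, estimate, se for the fixed
#'   effects), \code{cond_estimate} (the condition effect, second vs first
#'   level), \code{p_cond}, \code{p_interaction}, \code{n_trials},
#'   \code{excluded_sessions}, \code{messages} (convergence diagnostics;
#'   never silent), \code{fit}.
#' @export
fit_state_mixed_model <- function(table, condition_pair = c("Choice", "Miss"),
                                  with_interaction = FALSE, min_trials = 10L) {
  long <- if ("power_db" %in% names(table)) as.data.frame(table) else
    band_table_to_long(table)
  if (!"cond" %in% names(long)) {
    long$cond <- outcome_to_condition(long$outcome, condition_pair)
  }
  long <- long[long$cond %in% condition_pair & is.finite(long$power_db), ,
               drop = FALSE]
  stop_if(nrow(long) == 0L, "no trials in the requested conditions")
  long$cond <- factor(long$cond, levels = condition_pair)

  per_trial <- unique(long[, c("session_id", "trial", "cond")])
  cnt <- table(per_trial$session_id, per_trial$cond)
  bad <- rownames(cnt)[apply(cnt, 1, min) < min_trials]
  long <- long[!long$session_id %in% bad, , drop = FALSE]
  stop_if(nrow(long) == 0L,
          "every session has fewer than ", min_trials, " trials in a condition")

  long$area <- factor(long$area)
  long$genotype_id <- factor(long$genotype_id)
  long$subj_g <- interaction(long$subject_id, long$genotype_id, drop = TRUE)
  long$sess_sg <- interaction(long$session_id, long$subj_g, drop = TRUE)

  multi_area <- nlevels(long$area) > 1L
  fixed0 <- if (multi_area) "power_db ~ cond + area" else "power_db ~ cond"
  slope <- if (multi_area) "area" else "1"
  rand <- c(genotype_id = "genotype_id", subj = "subj_g", sess = "sess_sg")
  rand <- rand[vapply(rand, function(v) nlevels(long[[v]]) > 1L, logical(1))]
  rterms <- if (length(rand))
    paste(sprintf("(%s | %s)", slope, rand), collapse = " + ") else NULL

  messages <- character()
  fit_one <- function(rhs) {
    if (is.null(rterms)) return(stats::lm(stats::as.formula(rhs), data = long))
    withCallingHandlers(
      lme4::lmer(stats::as.formula(paste(rhs, "+", rterms)), data = long,
                 REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  lrt_p <- function(m0, m1) {
    a <- stats::anova(m0, m1)
    p <- a[["Pr(>Chisq)"]] %||% a[["Pr(>F)"]]
    p[2]
  }
  m1 <- fit_one(fixed0)
  m0 <- fit_one(sub("cond \\+ ", "", sub("~ cond$", "~ 1", fixed0)))
  p_cond <- lrt_p(m0, m1)
  p_int <- NA_real_
  fit <- m1
  if (with_interaction && multi_area) {
    m2 <- fit_one("power_db ~ cond * area")
    p_int <- lrt_p(m1, m2)
    fit <- m2
  }
  cf <- if (inherits(fit, "lm")) summary(fit)$coefficients else
    stats::coef(summary(fit))
  est <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                    row.names = NULL)
  cond_term <- paste0("cond", condition_pair[2])
  list(estimates = est,
       cond_estimate = est$estimate[est$term == cond_term],
       p_cond = p_cond, p_interaction = p_int,
       n_trials = nrow(unique(long[, c("session_id", "trial")])),
       excluded_sessions = bad, messages = messages, fit = fit)
}

# band_power_table (wide, one db_<ROI> column per area) -> long format
#' @noRd
band_table_to_long <- function(table) {
  rois <- names(attr(table, "rois"))
  stop_if(is.null(rois), "table lacks ROI metadata; supply a long data.frame")
  base <- as.data.frame(table)[, c("trial", "outcome", "session_id",
                                   "subject_id", "genotype_id")]
  do.call(rbind, lapply(rois, function(a) {
    cbind(base, area = a, power_db = table[[paste0("db_", a)]])
  }))
}

#' Logistic mixed model of behavior on power percentile
#'
#' Fits response ~ 1 + powerPercentile + (1 | session) with a logistic link:
#' the probability of a Miss (among stimulus trials), False Alarm (among
#' zero-contrast trials) or Incorrect choice (among non-equal-contrast
#' Choice trials) as a function of the ROI power percentile bin (1-5,
#' computed per session).
#'
#' @param table a \code{band_power_table} spanning >= 2 sessions.
#' @param roi ROI name.
#' @param response "Miss", "FalseAlarm" or "Incorrect".
#' @return list: \code{slope} (log-odds per percentile bin), \code{se},
#'   \code{ci} (Wald 95%), \code{p_value}, \code{n}, \code{separation}
#'   (TRUE when the fit is flagged as separated/degenerate).
#' @export
fit_percentile_glmm <- function(table, roi,
                                response = c("Miss", "FalseAlarm", "Incorrect")) {
  response <- match.arg(response)
  col <- paste0("power_", roi)
  tab <- table[is.finite(table[[col]]), , drop = FALSE]
  contrast <- tab$contrast_left > 0 | tab$contrast_right > 0
  choice <- tab$outcome %in% c("CorrectChoice", "IncorrectChoice")
  sel <- switch(response,
                Miss = contrast & (choice | tab$outcome == "Miss"),
                FalseAlarm = !contrast,
                Incorrect = contrast & choice &
                  tab$contrast_left != tab$contrast_right)
  tab <- tab[sel, , drop = FALSE]
  stop_if(nrow(tab) == 0L, "no trials define the ", response, " response")
  y <- switch(response,
              Miss = tab$outcome == "Miss",
              FalseAlarm = tab$outcome == "FalseAlarm",
              Incorrect = tab$outcome == "IncorrectChoice")
  stop_if(length(unique(y)) < 2L,
          "all responses identical: complete separation, no slope is estimable")
  pct <- stats::ave(tab[[col]], tab$session_id,
                    FUN = function(x) percentile_bins(x)$bin)
  dat <- data.frame(y = y, pct = pct, session = factor(tab$session_id))
  stop_if(nlevels(dat$session) < 2L, "need at least 2 sessions")
  separation <- FALSE
  fit <- withCallingHandlers(
    lme4::glmer(y ~ 1 + pct + (1 | session), data = dat, family = stats::binomial),
    warning = function(w) {
      if (grepl("converge|Hessian|deviance", conditionMessage(w), ignore.case = TRUE))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(summary(fit))
  slope <- cf["pct", "Estimate"]; se <- cf["pct", "Std. Error"]
  if (abs(slope) > 10) separation <- TRUE
  list(slope = slope, se = se,
       ci = slope + c(-1.96, 1.96) * se,
       p_value = cf["pct", "Pr(>|z|)"],
       n = nrow(dat), separation = separation, fit = fit)
}
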