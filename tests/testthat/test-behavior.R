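# Trial classification, quiescent windows, percentile curves, RT residuals,
# pupil ANCOVA, mixed models.

make_events <- function(cl, cr, resp, dir, rewarded = FALSE) {
  n <- length(cl)
  data.frame(contrast_left = cl, contrast_right = cr,
             gocue_s = rep(10, n), response_window_end_s = rep(13, n),
             response_s = resp, response_direction = dir, rewarded = rewarded)
}

test_that("trials classify by the task rules, invalid responses excluded", {
  ev <- make_events(cl = c(0,   0,   0.5, 0.5, 0,   0.5, 0.5, 0.5),
                    cr = c(0.5, 0,   0,   0,   0,   0.5, 0,   0),
                    resp = c(11,  NA,  11,  11,  11.5, 11, NA, 14),
                    dir = c(1,   0,  -1,   1,   1,    1,  0,  -1),
                    rewarded = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
                                 FALSE, FALSE))
  out <- suppressMessages(classify_trials(ev))
  expect_equal(out$outcome[1], "CorrectChoice")   # turn toward required side
  expect_equal(out$outcome[2], "CorrectReject")   # zero contrast, withheld
  expect_equal(out$outcome[3], "CorrectChoice")   # left stimulus, left turn
  expect_equal(out$outcome[4], "IncorrectChoice") # wrong direction
  expect_equal(out$outcome[5], "FalseAlarm")      # zero contrast, turned
  expect_equal(out$outcome[6], "CorrectChoice")   # equal contrast, rewarded
  expect_equal(out$outcome[7], "Miss")            # stimulus, no response
  expect_true(is.na(out$outcome[8]))              # response after window end
  expect_false(out$valid[8])
  expect_equal(attr(out, "n_invalid"), 1L)
})

test_that("quiescent windows: strict 0.7 s exclusion boundary and accounting", {
  tr <- data.frame(quiescent_start_s = c(1, 10, 20),
                   quiescent_end_s = c(1.6, 10.7, 21.9))
  qw <- extract_quiescent_windows(tr)
  expect_equal(qw$trial, c(2L, 3L))               # 0.6 out, exactly 0.7 in
  expect_equal(attr(qw, "n_excluded"), 1L)
  expect_equal(attr(qw, "n_included") + attr(qw, "n_excluded"), nrow(tr))

  empty <- extract_quiescent_windows(tr[0, ])
  expect_equal(nrow(empty), 0L)

  # trial-lag mode reads the following trial's window
  qw1 <- extract_quiescent_windows(tr, lag = 1L)
  expect_equal(qw1$start_s, c(10, 20))
})

test_that("percentile rates reproduce the worked bin arithmetic exactly", {
  pr <- percentile_rates(composed_table(), "VIS")
  r1 <- pr$rates[1, ]
  expect_equal(r1$N_trials, 50)
  expect_equal(r1$N_contrast, 40)
  expect_equal(r1$N_zero, 10)
  expect_equal(r1$N_choice, 36)
  expect_equal(r1$N_miss, 4)
  expect_equal(r1$N_nonequalContrast, 35)
  expect_equal(r1$N_correct, 28)
  expect_equal(r1$N_incorrect, 7)
  expect_equal(r1$N_reject, 6)
  expect_equal(r1$N_falsealarm, 4)
  expect_equal(r1$pct_choice, 90)
  expect_equal(r1$pct_miss, 10)
  expect_equal(r1$pct_correct, 80)
  expect_equal(r1$pct_incorrect, 20)
  expect_equal(r1$pct_reject, 60)
  expect_equal(r1$pct_falsealarm, 40)
  # complementarity invariants hold in every populated bin
  ok <- pr$rates$N_contrast > 0
  expect_equal(pr$rates$pct_choice[ok] + pr$rates$pct_miss[ok], rep(100, sum(ok)))
})

test_that("percentile binning: equal bins, degenerate outcomes, single-value warning", {
  df <- data.frame(outcome = rep(c("CorrectChoice", "IncorrectChoice"), 50),
                   contrast_left = 0, contrast_right = 0.5,
                   session_id = "s1", power_VIS = as.numeric(1:100))
  class(df) <- c("band_power_table", "data.frame")
  pr <- percentile_rates(df, "VIS")
  expect_equal(pr$rates$N_trials, rep(20, 5))     # 1..100 -> bins of 20
  expect_true(all(pr$rates$pct_miss[pr$rates$N_contrast > 0] == 0))

  dfc <- df; dfc$power_VIS <- 1
  expect_warning(percentile_rates(dfc, "VIS"), "identical")
  expect_error(percentile_rates(df[1:4, ], "VIS"), "at least 5")
})

test_that("reaction-time residual correlation recovers a generative power effect", {
  gen_tab <- function(seed, beta) {
    set.seed(seed)
    n <- 120
    contrast <- sample(c(0.25, 0.5, 1), n, replace = TRUE)
    power <- runif(n, 0, 2)
    df <- data.frame(outcome = "CorrectChoice", contrast_left = 0,
                     contrast_right = contrast, session_id = "s1",
                     reaction_time_s = 0.3 + 0.4 * (1 - contrast) +
                       beta * power + rnorm(n, 0, 0.05),
                     power_VIS = power)
    class(df) <- c("band_power_table", "data.frame")
    df
  }
  hits <- sum(vapply(1:6, function(sd) {
    rt_power_correlation(gen_tab(sd, 0.05), "VIS")$r > 0
  }, logical(1)))
  expect_gte(hits, 6L * 0.95)

  # permutation null: shuffled power decorrelates
  rs <- vapply(1:8, function(sd) {
    tab <- gen_tab(sd, 0.05)
    set.seed(sd + 100)
    tab$power_VIS <- sample(tab$power_VIS)
    rt_power_correlation(tab, "VIS")$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 2 / sqrt(120))

  # identical RTs within contrast: zero-variance residuals signalled
  tab0 <- gen_tab(1, 0)
  tab0$reaction_time_s <- 0.3 + tab0$contrast_right
  expect_warning(rt_power_correlation(tab0, "VIS"), "undefined")
  res <- suppressWarnings(rt_power_correlation(tab0, "VIS"))
  expect_true(res$undefined)
  expect_true(is.na(res$r))
})

ancova_tab <- function(seed, delta, beta = 2) {
  set.seed(seed)
  n <- 160
  miss <- rep(c(FALSE, TRUE), length.out = n)
  pupil <- rnorm(n, 3, 0.4)
  df <- data.frame(outcome = ifelse(miss, "Miss", "CorrectChoice"),
                   contrast_left = 0, contrast_right = 0.5, session_id = "s1",
                   pupil_mean = pupil, pupil_derivative_mean = rnorm(n),
                   db_VIS = beta * pupil + delta * miss + rnorm(n, 0, 0.8))
  class(df) <- c("band_power_table", "data.frame")
  df
}

test_that("pupil ANCOVA: parallel lines, null behavior, effect recovery", {
  a <- pupil_ancova(ancova_tab(1, delta = 1.2), "VIS")
  expect_equal(diff(a$intercepts), a$intercept_difference,
               ignore_attr = TRUE)

  # recovery: estimate within 2 SE of the generative offset in most seeds
  hits <- sum(vapply(1:5, function(sd) {
    a <- pupil_ancova(ancova_tab(sd, delta = 1.2), "VIS")
    se <- a$intercept_difference / qnorm(1 - a$p_value / 2)
    abs(a$intercept_difference - 1.2) < 2 * abs(se) + 0.3
  }, logical(1)))
  expect_gte(hits, 4L)

  # null: no intercept difference beyond noise
  null_hits <- sum(vapply(1:5, function(sd) {
    pupil_ancova(ancova_tab(sd + 50, delta = 0), "VIS")$p_value > 0.01
  }, logical(1)))
  expect_gte(null_hits, 4L)

  expect_error(pupil_ancova(ancova_tab(1, 0)[c(TRUE, FALSE), ], "VIS"),
               "at least 3")
})

test_that("nested mixed model collapses to OLS for a single session", {
  tab <- simulate_band_power_table(n_genotypes = 1, subjects_per_genotype = 1,
                                   sessions_per_subject = 1,
                                   trials_per_session = 80,
                                   cond_effect_db = -1, seed = 5)
  r <- fit_state_mixed_model(tab)
  ols <- lm(power_db ~ cond + area, data = transform(tab, cond = factor(cond,
            c("Choice", "Miss")), area = factor(area)))
  expect_lt(max(abs(r$estimates$estimate - unname(coef(ols)))), 1e-6)
})

test_that("nested mixed model recovers an injected condition effect", {
  r <- fit_state_mixed_model(simulate_band_power_table(cond_effect_db = -1.5,
                                                       seed = 6))
  expect_lt(abs(r$cond_estimate - (-1.5)), 0.3)
  expect_lt(r$p_cond, 0.05)
  # interaction test runs and reports
  r2 <- fit_state_mixed_model(simulate_band_power_table(cond_effect_db = -1.5,
                                                        trials_per_session = 40,
                                                        seed = 7),
                              with_interaction = TRUE)
  expect_true(is.finite(r2$p_interaction))
})

test_that("mixed-model session exclusion drops under-sampled sessions", {
  tab <- simulate_band_power_table(trials_per_session = 40, seed = 8)
  # force one session to have almost no Miss trials
  s1 <- tab$session_id == tab$session_id[1] & tab$cond == "Miss"
  tab2 <- tab[!s1 | seq_len(nrow(tab)) %in% which(s1)[1:5], ]
  r <- fit_state_mixed_model(tab2)
  expect_true(tab$session_id[1] %in% r$excluded_sessions)
})

glmm_tab <- function(seed, slope, n_sessions = 6, n_per = 150) {
  set.seed(seed)
  rows <- lapply(seq_len(n_sessions), function(si) {
    power <- runif(n_per)
    pct <- findInterval(power, quantile(power, c(.2, .4, .6, .8), type = 5)) + 1
    off <- rnorm(1, 0, 0.3)
    y <- runif(n_per) < plogis(-1.8 + slope * pct + off)
    data.frame(outcome = ifelse(y, "Miss", "CorrectChoice"),
               contrast_left = 0, contrast_right = 0.5,
               session_id = sprintf("s%02d", si), power_VIS = power)
  })
  df <- do.call(rbind, rows)
  class(df) <- c("band_power_table", "data.frame")
  df
}

test_that("percentile GLMM recovers slope sign and flags degenerate input", {
  r <- fit_percentile_glmm(glmm_tab(1, 0.4), "VIS", "Miss")
  expect_gt(r$slope, 0)
  expect_gt(r$ci[1], 0)                            # CI excludes 0

  r0 <- fit_percentile_glmm(glmm_tab(2, 0), "VIS", "Miss")
  expect_true(r0$ci[1] < 0 && r0$ci[2] > 0)

  tab_const <- glmm_tab(3, 0.4)
  tab_const$outcome <- "Miss"
  expect_error(fit_percentile_glmm(tab_const, "VIS", "Miss"), "separation")
})

test_that("band-power tables carry exclusion accounting and dB columns", {
  s <- small_session()
  cal <- small_session_stores()$cal
  tab <- band_power_table(cal, classify_trials(s$trials), default_roi_set(16),
                          pupil = s$pupil)
  prov <- attr(tab, "provenance")
  expect_equal(prov$n_included + prov$n_excluded + prov$n_invalid, prov$n_raw)
  expect_true(all(c("power_VIS", "db_VIS", "power_MO", "pupil_mean") %in%
                    names(tab)))
  expect_lt(abs(mean(tab$db_VIS)), 1e-9)           # dB relative to session mean
  expect_true(all(tab$power_VIS >= 0))
  expect_equal(tab$reaction_time_s,
               tab$response_s - tab$gocue_s)
})
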