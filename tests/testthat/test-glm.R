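test_that("event screening drops unattended and extremely premature cues but keeps outcomes", {
  log <- make_log(matrix(50, 3, 4), rt_by_type = matrix(250, 1, 4))
  ev <- screen_events(log)
  expect_true(all(ev$cue_included))            # every trial answered in time
  expect_equal(nrow(ev), nrow(log$trials))     # one outcome event per trial
  expect_equal(ev$magnitude_pence, log$trials$payout_pence)

  # omission: cue dropped, outcome retained
  log2 <- log
  log2$trials$rt_ms[5] <- NA
  log2$trials$classification[5] <- "omitted"
  ev2 <- screen_events(log2)
  expect_false(ev2$cue_included[5])
  expect_equal(nrow(ev2), nrow(ev))

  # a response 900 ms after cue onset is extremely premature: cue dropped
  log3 <- log
  log3$trials$probe_onset_s[7] <- log3$trials$cue_onset_s[7] + 0.5
  log3$trials$rt_ms[7] <- 400   # 900 ms after cue onset
  ev3 <- screen_events(log3)
  expect_false(ev3$cue_included[7])
  expect_true(ev3$cue_included[6])
})

test_that("the haemodynamic basis has the canonical double-gamma shape", {
  b <- hrf_basis(0.01)
  # peak of the response gamma: mode of Gamma(shape 6, scale 1) = 5 s
  expect_lt(abs(b$time_s[which.max(b$canonical)] - 5), 0.011)
  expect_equal(max(b$canonical), 1)                     # unit-peak convention
  expect_lt(abs(sum(b$temporal) * 0.01), 0.005)         # derivative sums to ~0
  expect_equal(b$canonical[1], 0)
  # undershoot: negative lobe after ~10 s
  expect_lt(min(b$canonical[b$time_s > 10]), 0)
  expect_error(hrf_basis(0), "positive")
})

test_that("the design matrix has the documented column structure", {
  lr <- make_long_run_events(seed = 3)
  ev <- lr$events[lr$events$cue_onset_s < 295 * 2.73 - 40, ]
  d <- build_design(ev, n_scans = 300, tr = 2.73)
  k <- floor(2 * 300 * 2.73 / 128)
  expect_equal(k, 12)
  expect_equal(ncol(d$X), 6 * 3 + k + 1)
  expect_equal(sum(d$columns$task), 18)
  expect_equal(unname(d$X[, "intercept"]), rep(1, 300))
  expect_false(any(d$columns$empty))

  # a condition with no events yields all-zero, flagged columns
  ev_no_red <- ev
  ev_no_red$cue_included[ev_no_red$cue_type == "red_animal"] <- FALSE
  d2 <- build_design(ev_no_red, n_scans = 300, tr = 2.73)
  red_cols <- d2$columns$condition == "cue_red_animal"
  expect_true(all(d2$columns$empty[red_cols]))
  expect_true(all(d2$X[, red_cols] == 0))

  # events beyond the run end are rejected
  expect_error(build_design(ev, n_scans = 60, tr = 2.73), "beyond")
})

test_that("shifting all onsets by one TR shifts task columns by one scan", {
  lr <- make_long_run_events(seed = 4)
  ev <- lr$events[lr$events$cue_onset_s < 420 * 2.73 - 40, ]
  d0 <- build_design(ev, n_scans = 430, tr = 2.73)
  ev_shift <- ev
  ev_shift$cue_onset_s <- ev_shift$cue_onset_s + 2.73
  ev_shift$outcome_onset_s <- ev_shift$outcome_onset_s + 2.73
  d1 <- build_design(ev_shift, n_scans = 430, tr = 2.73)
  task <- d0$columns$name[d0$columns$task]
  rows <- 5:425
  expect_equal(d1$X[rows + 1, task], d0$X[rows, task], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the GLM recovers exact coefficients from noiseless data", {
  lr <- make_long_run_events(seed = 5)
  d <- build_design(lr$events, n_scans = 500, tr = 2.73)
  set.seed(1)
  b <- rnorm(ncol(d$X))
  Y <- d$X %*% cbind(b, -0.5 * b)
  fit <- fit_glm(Y, d)
  expect_lt(max(abs(fit$betas[, 1] - b)), 1e-8)
  expect_lt(max(abs(fit$betas[, 2] + 0.5 * b)), 1e-8)
})

test_that("the pooled AR(1) estimate is calibrated", {
  lr <- make_long_run_events(seed = 6)
  d <- build_design(lr$events, n_scans = 500, tr = 2.73)
  cal <- ar1_calibration(d)
  gen <- function(rho, seed, n_vox = 10) {
    withr::with_seed(seed, {
      e <- matrix(rnorm(500 * n_vox), 500)
      if (rho > 0) for (t in 2:500) e[t, ] <- rho * e[t - 1, ] + e[t, ] * sqrt(1 - rho^2)
      e
    })
  }
  for (rho in c(0, 0.3)) {
    est <- vapply(1:10, function(s) {
      fit_glm(gen(rho, s), d, ar_calibration = cal)$rho
    }, numeric(1))
    expect_lt(abs(mean(est) - rho), 0.05)
    expect_true(all(abs(est - rho) < 0.08))
  }
})

test_that("rank-deficient designs are rejected with the offending columns named", {
  X <- cbind(a = rnorm(50), b = rnorm(50))
  X <- cbind(X, c = X[, 1] + X[, 2])
  expect_error(fit_glm(matrix(rnorm(50), 50), X), "rank deficient.*c")
})

test_that("contrasts recover injected signals and obey their symmetries", {
  lr <- make_long_run_events(seed = 7)
  d <- build_design(lr$events, n_scans = 500, tr = 2.73)
  X <- d$X
  version <- lr$version
  relabel_high <- lr$relabel$subjective_high

  w_ad <- contrast_weights(d, "adaptive", version)
  w_ab <- contrast_weights(d, "aberrant", version, relabel_high = relabel_high)
  w_pm <- contrast_weights(d, "parametric_outcome")
  expect_equal(sum(w_ad != 0), 4)
  expect_equal(sum(w_ad), 0)
  expect_equal(sum(w_pm), 1)

  inject <- function(w, c_amp) X %*% (pmax(w, 0) * 2 * c_amp)  # +c on each +1/2 column
  amp <- 1.7
  Y <- cbind(
    adaptive = inject(w_ad, amp),
    parametric = X[, "outcome_mag:hrf", drop = FALSE] * amp
  )
  fit <- fit_glm(Y, d)
  ad <- apply_contrast(fit, "adaptive", version = version)
  pm <- apply_contrast(fit, "parametric_outcome")
  expect_equal(ad$value[1], amp, tolerance = 1e-6)
  expect_equal(pm$value[2], amp, tolerance = 1e-6)

  # aberrant contrast: symmetric responses cancel; flipping the relabelling
  # flips the sign
  Y_ab <- inject(w_ab, amp)
  fit_ab <- fit_glm(cbind(Y_ab), d)
  ab <- apply_contrast(fit_ab, "aberrant", version = version,
                       relabel_high = relabel_high)
  expect_equal(ab$value, amp, tolerance = 1e-6)
  other <- setdiff(dimension_levels(version$irrelevant_dimension), relabel_high)
  ab_flip <- apply_contrast(fit_ab, "aberrant", version = version,
                            relabel_high = other)
  expect_equal(ab_flip$value, -amp, tolerance = 1e-6)

  # equal response to both irrelevant levels: aberrant contrast ~ 0
  Y_sym <- X %*% (abs(w_ab) * 2 * amp)
  fit_sym <- fit_glm(cbind(Y_sym), d)
  ab_sym <- apply_contrast(fit_sym, "aberrant", version = version,
                           relabel_high = relabel_high)
  expect_lt(abs(ab_sym$value), 1e-6)

  # a tied relabelling still evaluates, with a warning
  expect_warning(
    apply_contrast(fit_ab, "aberrant", version = version,
                   relabel_high = relabel_high, relabel_tie = TRUE),
    "tie"
  )
})

test_that("drift terms absorb slow trends without biasing contrasts", {
  lr <- make_long_run_events(seed = 8)
  d <- build_design(lr$events, n_scans = 434, tr = 2.73)
  X <- d$X
  version <- lr$version
  w_ad <- contrast_weights(d, "adaptive", version)
  amp <- 2
  base <- X %*% (pmax(w_ad, 0) * 2 * amp)
  slow <- 3 * sin(2 * pi * d$frame_times / 400)   # period 400 s > 128 s cutoff
  fit0 <- fit_glm(cbind(base), d)
  fit1 <- fit_glm(cbind(base + slow), d)
  c0 <- apply_contrast(fit0, "adaptive", version = version)$value
  c1 <- apply_contrast(fit1, "adaptive", version = version)$value
  expect_equal(c0, amp, tolerance = 1e-6)
  expect_lt(abs(c1 - c0), 0.02 * amp)
})

test_that("the full first-level pipeline produces three contrasts per subject", {
  cal <- ref_calibration()
  sched <- build_schedule("blue", seed = 21, calibration = cal)
  log <- emit_behavior(sched, agent_params(), seed = 22)
  n_scans <- 220
  bold <- withr::with_seed(23, lapply(1:3, function(b) matrix(rnorm(n_scans * 6), n_scans)))
  fl <- fit_first_level(log, bold, tr = 2.73)
  expect_equal(dim(fl$contrasts), c(6, 3))
  expect_equal(colnames(fl$contrasts),
               c("parametric_outcome", "adaptive", "aberrant"))
  expect_length(fl$fits, 3)
  expect_equal(nrow(fl$relabel), 3)
  # design matrix construction is deterministic
  fl2 <- fit_first_level(log, bold, tr = 2.73)
  expect_identical(fl$contrasts, fl2$contrasts)
})
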