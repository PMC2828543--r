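# ratings matrices are blocks x cue types in the order
# blue_animal, blue_object, red_animal, red_object

test_that("explicit measures are level-rating differences on the stated definitions", {
  # high-relevant (blue) rated 70/80, low-relevant (red) 30/40 in each block
  ratings <- matrix(c(70, 80, 30, 40), 3, 4, byrow = TRUE)
  m <- score_subject(make_log(ratings))
  expect_equal(m$adaptive_explicit_mm, rep((70 + 80) / 2 - (30 + 40) / 2, 3))
  expect_equal(m$adaptive_explicit_mm, rep(40, 3))
  # animal level = (70 + 30)/2 = 50, object = (80 + 40)/2 = 60
  expect_equal(m$aberrant_explicit_mm, rep(10, 3))
  expect_equal(m$relabel_high, rep("object", 3))

  # irrelevant levels 60 vs 40 exactly
  r2 <- matrix(c(60, 40, 60, 40), 3, 4, byrow = TRUE)
  m2 <- score_subject(make_log(r2))
  expect_equal(m2$aberrant_explicit_mm, rep(20, 3))
  expect_equal(m2$relabel_high, rep("animal", 3))
  expect_false(any(m2$relabel_tie))
})

test_that("identical ratings give zero explicit measures and a flagged tie", {
  m <- score_subject(make_log(matrix(50, 3, 4)))
  expect_equal(m$adaptive_explicit_mm, rep(0, 3))
  expect_equal(m$aberrant_explicit_mm, rep(0, 3))
  expect_true(all(m$relabel_tie))
  # canonical tie-break: first level of the irrelevant dimension (animal)
  expect_equal(m$relabel_high, rep("animal", 3))
})

test_that("subjective relabelling is block-specific and sign-consistent", {
  ratings <- rbind(
    c(70, 50, 60, 40),  # animal = 65 > object = 45
    c(50, 70, 40, 60),  # object higher: relabel flips within subject
    c(70, 50, 60, 40)
  )
  log <- make_log(ratings)
  rl <- subjective_relabel(log)
  expect_equal(rl$subjective_high, c("animal", "object", "animal"))
  expect_equal(rl$subjective_low, c("object", "animal", "object"))
  m <- score_subject(log)
  expect_equal(m$relabel_high, rl$subjective_high)
  # aberrant explicit equals |signed difference| and the sign matches relabel
  expect_equal(m$aberrant_explicit_mm, rep(20, 3))
})

test_that("implicit measures use valid RTs only and respect the sign conventions", {
  # blue (high) responded at 230 ms, red (low) at 250: adaptive = +20 ms
  # (all RTs sit inside every probe window, so every trial is valid)
  rt <- matrix(c(230, 230, 250, 250), 1, 4)
  log <- make_log(matrix(c(70, 70, 30, 30), 3, 4, byrow = TRUE), rt_by_type = rt)
  m <- score_subject(log)
  expect_equal(m$adaptive_implicit_ms, rep(20, 3))
  expect_equal(m$aberrant_implicit_ms, rep(0, 3))

  rt2 <- matrix(c(230, 240, 230, 240), 1, 4)  # animal faster by 10 ms
  m2 <- score_subject(make_log(matrix(50, 3, 4), rt_by_type = rt2))
  expect_equal(m2$aberrant_implicit_ms, rep(10, 3))
  expect_equal(m2$adaptive_implicit_ms, rep(0, 3))
})

test_that("scoring is invariant to the counterbalanced version labelling", {
  # same subject seen through the "blue high" and "red high" versions with
  # the colour ratings swapped: measures must coincide
  r_blue <- rbind(c(72, 64, 31, 25), c(80, 70, 28, 22), c(85, 75, 20, 18))
  r_red <- r_blue[, c(3, 4, 1, 2)]
  rt <- matrix(c(238, 242, 256, 251), 1, 4)
  m_blue <- score_subject(make_log(r_blue, rt_by_type = rt))
  m_red <- score_subject(make_log(r_red, rt_by_type = rt[, c(3, 4, 1, 2), drop = FALSE],
                                  version = task_version("red")))
  for (col in c("adaptive_explicit_mm", "aberrant_explicit_mm",
                "adaptive_implicit_ms", "aberrant_implicit_ms")) {
    expect_equal(m_blue[[col]], m_red[[col]], tolerance = 1e-10)
  }
})

test_that("binary outcome entropy matches its closed form and symmetries", {
  expect_equal(round(outcome_entropy(0.875), 3), 0.377)
  expect_equal(round(outcome_entropy(0.5), 3), 0.693)
  expect_equal(outcome_entropy(1), 0)
  expect_equal(outcome_entropy(0), 0)
  p <- seq(0, 1, by = 0.01)
  expect_equal(outcome_entropy(p), outcome_entropy(1 - p))
  expect_equal(p[which.max(outcome_entropy(p))], 0.5)
  expect_error(outcome_entropy(1.2), "\\[0, 1\\]")
})

test_that("leave-one-out outlier exclusion removes only extreme subjects", {
  set.seed(1)
  d <- tibble::tibble(subject = 1:20,
                      m = c(rnorm(19, 6.5, 1), -40))
  res <- exclude_outliers(d, m)
  expect_equal(res$subject[res$excluded], 20)
  # leave-one-out z computed against the *other* subjects
  z20 <- (d$m[20] - mean(d$m[-20])) / sd(d$m[-20])
  expect_equal(res$loo_z[20], z20)

  homog <- tibble::tibble(subject = 1:10, m = rnorm(10, 5, 0.5))
  expect_false(any(exclude_outliers(homog, m)$excluded))
  expect_false(any(exclude_outliers(d, m, threshold_sd = Inf)$excluded))
  expect_error(exclude_outliers(d[1:2, ], m), "at least 3")
})

test_that("earnings summaries aggregate payouts and error counts correctly", {
  log <- make_log(matrix(50, 3, 4), rt_by_type = matrix(250, 1, 4))
  es <- summarize_earnings(log)
  # totals equal the sum of trial payouts
  tot <- tapply(log$trials$payout_pence, log$trials$block, sum)
  expect_equal(es$by_block$total_pence, as.vector(tot))
  # rt 250 ms is 50 ms (2.5 SDF) faster than the mean: X = 10 + 90*50/60 = 85
  expect_true(all(es$by_condition$mean_payout_pence == 85))
  expect_equal(
    es$by_condition$n_rewarded[es$by_condition$condition == "relevant_high"],
    rep(28, 3)
  )
  expect_true(all(es$errors$premature == 0) && all(es$errors$omissions == 0))

  # order invariance
  log_shuf <- log
  perm <- withr::with_seed(3, sample(nrow(log$trials)))
  log_shuf$trials <- log$trials[perm, ]
  es2 <- summarize_earnings(log_shuf)
  expect_equal(es2$by_block, es$by_block)
  expect_equal(dplyr::arrange(es2$by_condition, block, condition),
               dplyr::arrange(es$by_condition, block, condition))
})

test_that("payout means by condition follow hand arithmetic on a toy log", {
  log <- make_log(matrix(50, 3, 4))
  # overwrite with a minimal hand-made trial set: 2 rewarded high trials
  # paying 40 and 100, 2 rewarded low trials paying 5 and 10
  log$trials <- tibble::tibble(
    block = 1L, cue_type = c("blue_animal", "blue_object", "red_animal", "red_object"),
    color = c("blue", "blue", "red", "red"),
    shape = c("animal", "object", "animal", "object"),
    relevant_level = c("high", "high", "low", "low"),
    rewarded = TRUE,
    payout_pence = c(40L, 100L, 5L, 10L),
    classification = "valid"
  )
  es <- summarize_earnings(log)
  bc <- es$by_condition
  expect_equal(bc$mean_payout_pence[bc$condition == "relevant_high"], 70)
  expect_equal(bc$mean_payout_pence[bc$condition == "relevant_low"], 7.5)
})

test_that("cohort statistics compute one-sample t-tests and correlations", {
  measures <- tibble::tibble(
    subject = sprintf("s%d", 1:5), block = 1L,
    adaptive_explicit_mm = c(1, 2, 3, 4, 5),
    aberrant_explicit_mm = 2 * c(1, 2, 3, 4, 5),   # perfectly linear pair
    adaptive_implicit_ms = c(0, 0, 0, 0, 0),       # zero variance
    aberrant_implicit_ms = c(5, 1, 4, 2, 3)
  )
  st <- cohort_stats(measures)
  t_adaptive <- st$tests$t[st$tests$measure == "adaptive_explicit_mm"]
  expect_equal(round(t_adaptive, 3), 4.243)  # mean/(sd/sqrt(5)) = 3/(1.5811/2.236)
  expect_true(st$tests$degenerate[st$tests$measure == "adaptive_implicit_ms"])
  r_pair <- st$correlations$r[st$correlations$measure_1 == "adaptive_explicit_mm" &
                              st$correlations$measure_2 == "aberrant_explicit_mm"]
  expect_equal(r_pair, 1)
  expect_s3_class(tidy(st), "tbl_df")
})

test_that("paired block contrasts detect a block effect", {
  subj <- sprintf("s%d", 1:8)
  measures <- dplyr::bind_rows(lapply(1:3, function(b) {
    tibble::tibble(subject = subj, block = b,
                   adaptive_explicit_mm = 10 * b + seq(0, 0.7, 0.1),
                   aberrant_explicit_mm = 5 + seq(0, 0.7, 0.1),
                   adaptive_implicit_ms = 1, aberrant_implicit_ms = 1)
  }))
  st <- cohort_stats(measures)
  bc <- st$block_contrasts
  row <- bc[bc$measure == "adaptive_explicit_mm" & bc$block_a == 1 & bc$block_b == 2, ]
  expect_true(row$degenerate)  # constant difference of exactly -10
  row13 <- bc[bc$measure == "aberrant_explicit_mm" & bc$block_a == 1 & bc$block_b == 3, ]
  expect_true(row13$degenerate || row13$p > 0.9)
})
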