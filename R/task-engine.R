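#' Task version of the Salience Attribution Test
#'
#' The SAT uses compound cues varying on colour (blue/red) and shape
#' (animal/household object). One dimension is task-relevant: one of its
#' levels (the "high feature") signals an 87.5% probability of monetary
#' reward and the other 12.5%. The other dimension is task-irrelevant (both
#' levels rewarded at 50%). Four counterbalanced versions exist, one per
#' possible high feature.
#'
#' @param high_feature One of `"blue"`, `"red"`, `"animal"`, `"object"`: the
#'   cue feature rewarded with high probability. The task-relevant dimension
#'   is implied (colour for blue/red, shape for animal/object).
#' @return A `sat_version` object: a list with `relevant_dimension`,
#'   `irrelevant_dimension`, `high_feature` and `low_feature`.
#' @examples
#' task_version("blue")
#' @export
task_version <- function(high_feature = c("blue", "red", "animal", "object")) {
  high_feature <- match.arg(high_feature)
  rel <- feature_dimension(high_feature)
  lev <- dimension_levels(rel)
  structure(
    list(
      relevant_dimension = rel,
      irrelevant_dimension = other_dimension(rel),
      high_feature = high_feature,
      low_feature = setdiff(lev, high_feature)
    ),
    class = "sat_version"
  )
}

#' @export
print.sat_version <- function(x, ...) {
  cat("<SAT version> relevant dimension:", x$relevant_dimension,
      "| high-probability feature:", x$high_feature, "\n")
  invisible(x)
}

#' All four counterbalanced task versions
#' @return A named list of the four [task_version()] objects.
#' @export
sat_versions <- function() {
  feats <- c("blue", "red", "animal", "object")
  stats::setNames(lapply(feats, task_version), feats)
}

#' Calibrate per-subject timing parameters from practice reaction times
#'
#' Before the main game each subject performs a practice session (speeded
#' responses to the probe, no cues, no reward). Two quantities are derived:
#' the mean reaction time over all valid practice trials, and the standard
#' deviation of the ten fastest trials (SDF). Both parameterise the payout
#' rule and the probe duration window in the main game.
#'
#' Practice responses are "valid" if present (not `NA`) and at least 100 ms
#' after probe onset (faster responses are premature anticipations). The SDF
#' uses the sample standard deviation (n - 1 denominator) of the ten smallest
#' valid RTs.
#'
#' @param practice_rts Numeric vector of practice reaction times in
#'   milliseconds, measured from probe onset. `NA` marks omissions.
#' @return A `sat_calibration` object: list with `mean_rt_ms`, `sdf_ms`, and
#'   `n_valid`.
#' @examples
#' calibrate(c(280, 285, 290, 295, 300, 305, 310, 315, 320, 325, 400, 450))
#' @export
calibrate <- function(practice_rts) {
  stopifnot(is.numeric(practice_rts))
  valid <- practice_rts[!is.na(practice_rts) & practice_rts >= 100]
  if (any(practice_rts < 0, na.rm = TRUE)) {
    abort("practice reaction times must be non-negative")
  }
  if (length(valid) < 10) {
    abort(sprintf(
      "calibration needs at least 10 valid practice trials, got %d",
      length(valid)
    ), class = "satlearn_insufficient_data")
  }
  fastest <- sort(valid)[1:10]
  sdf <- sd(fastest)
  if (sdf <= 0) {
    abort("the ten fastest practice trials are identical; SDF would be zero",
          class = "satlearn_degenerate_calibration")
  }
  structure(
    list(mean_rt_ms = mean(valid), sdf_ms = sdf, n_valid = length(valid)),
    class = "sat_calibration"
  )
}

#' @export
print.sat_calibration <- function(x, ...) {
  cat(sprintf("<SAT calibration> mean RT %.1f ms, SDF %.2f ms (%d valid trials)\n",
              x$mean_rt_ms, x$sdf_ms, x$n_valid))
  invisible(x)
}

#' Construct a calibration profile directly
#'
#' Convenience constructor when the practice summary statistics are already
#' known (e.g. from a calibration file) rather than raw practice RTs.
#'
#' @param mean_rt_ms Mean practice reaction time, milliseconds (> 0).
#' @param sdf_ms Standard deviation of the ten fastest practice trials,
#'   milliseconds (> 0).
#' @return A `sat_calibration` object.
#' @export
calibration_profile <- function(mean_rt_ms, sdf_ms) {
  stopifnot(is.numeric(mean_rt_ms), is.numeric(sdf_ms))
  if (mean_rt_ms <= 0 || sdf_ms <= 0) {
    abort("mean_rt_ms and sdf_ms must both be positive")
  }
  structure(
    list(mean_rt_ms = mean_rt_ms, sdf_ms = sdf_ms, n_valid = NA_integer_),
    class = "sat_calibration"
  )
}

# The fixed trial timeline (seconds). A fixation cross opens the trial; the
# cue appears 1 s later and stays until trial end; the probe replaces the
# fixation cross 3.5-4.5 s after cue onset; feedback follows 2.25 s after
# probe onset and lasts 1.5 s; trials are spaced at a constant 9.25 s.
SAT_ITI_S <- 9.25
SAT_CUE_DELAY_S <- 1
SAT_FEEDBACK_DELAY_S <- 2.25
SAT_FEEDBACK_DUR_S <- 1.5
SAT_CUE_MODEL_DUR_S <- 2
SAT_TRIALS_PER_BLOCK <- 64L
SAT_N_BLOCKS <- 3L

#' Generate a full SAT trial schedule
#'
#' Builds the 3-block x 64-trial design. Each block presents each of the 64
#' distinct stimuli (4 cue types x 16 pictures) exactly once in a uniformly
#' shuffled order. Reward availability is assigned without replacement within
#' each cue type: 14/16 trials rewarded for the two cue types carrying the
#' high-probability relevant feature, 2/16 for the two carrying the
#' low-probability feature — so exactly 32/64 trials per block are rewarded
#' and each irrelevant-dimension level is rewarded on 16/32 of its trials.
#' The probe-onset delay is drawn uniformly on 3.5–4.5 s after cue onset and
#' the probe duration uniformly on `mean_rt ± 2 SDF` from the subject's
#' calibration. Trial onsets are spaced at a constant 9.25 s within each
#' block; each block restarts at 0 s (one scanner run per block).
#'
#' Randomisation is reproducible: every component (per-block reward
#' assignment, trial order, probe delays, probe durations) consumes its own
#' stream derived from `seed`.
#'
#' @param version A [task_version()] object (or a feature name coerced to one).
#' @param seed Integer master seed.
#' @param calibration A `sat_calibration` object.
#' @return A `sat_schedule` object: list with `version`, `calibration`,
#'   `seed`, and `trials`, a tibble with one row per trial (columns `block`,
#'   `index_in_block`, `color`, `shape`, `picture_id`, `cue_type`,
#'   `relevant_level`, `rewarded`, `onset_s`, `cue_onset_s`, `probe_delay_s`,
#'   `probe_onset_s`, `probe_duration_ms`).
#' @examples
#' sched <- build_schedule(task_version("blue"), seed = 1,
#'                         calibration = calibration_profile(300, 20))
#' dplyr::count(sched$trials, block, rewarded)
#' @export
build_schedule <- function(version, seed, calibration) {
  if (is.character(version)) version <- task_version(version)
  if (!inherits(version, "sat_version")) abort("`version` must be a sat_version")
  if (!inherits(calibration, "sat_calibration")) {
    abort("`calibration` must be a sat_calibration")
  }
  seed <- as.integer(seed)

  cue_grid <- tidyr::expand_grid(
    color = c("blue", "red"),
    shape = c("animal", "object"),
    picture_id = 1:16
  )

  blocks <- purrr::map(seq_len(SAT_N_BLOCKS), function(b) {
    trials <- cue_grid
    trials$cue_type <- paste(trials$color, trials$shape, sep = "_")
    rel_feature <- trials[[version$relevant_dimension]]
    trials$relevant_level <-
      ifelse(rel_feature == version$high_feature, "high", "low")

    # 14/16 rewarded at the high relevant feature, 2/16 at the low, sampled
    # without replacement within each cue type, with a block-specific stream.
    trials <- withr::with_seed(
      substream_seed(seed, paste0("rewards-block-", b)),
      trials |>
        dplyr::group_by(.data$cue_type) |>
        dplyr::mutate(rewarded = {
          n_rew <- if (.data$relevant_level[1] == "high") 14L else 2L
          seq_len(dplyr::n()) %in% sample.int(dplyr::n(), n_rew)
        }) |>
        dplyr::ungroup()
    )

    ord <- withr::with_seed(
      substream_seed(seed, paste0("order-block-", b)),
      sample.int(nrow(trials))
    )
    trials <- trials[ord, ]
    trials$block <- b
    trials$index_in_block <- seq_len(nrow(trials))
    trials$onset_s <- (trials$index_in_block - 1) * SAT_ITI_S
    trials$cue_onset_s <- trials$onset_s + SAT_CUE_DELAY_S
    trials$probe_delay_s <- withr::with_seed(
      substream_seed(seed, paste0("probe-delay-block-", b)),
      runif(nrow(trials), 3.5, 4.5)
    )
    trials$probe_onset_s <- trials$cue_onset_s + trials$probe_delay_s
    trials$probe_duration_ms <- withr::with_seed(
      substream_seed(seed, paste0("probe-duration-block-", b)),
      runif(nrow(trials),
            calibration$mean_rt_ms - 2 * calibration$sdf_ms,
            calibration$mean_rt_ms + 2 * calibration$sdf_ms)
    )
    trials
  })

  trials <- dplyr::bind_rows(blocks) |>
    dplyr::select(
      "block", "index_in_block", "color", "shape", "picture_id", "cue_type",
      "relevant_level", "rewarded", "onset_s", "cue_onset_s",
      "probe_delay_s", "probe_onset_s", "probe_duration_ms"
    )

  structure(
    list(version = version, calibration = calibration, seed = seed,
         trials = trials),
    class = "sat_schedule"
  )
}

#' @export
print.sat_schedule <- function(x, ...) {
  cat(sprintf(
    "<SAT schedule> %d blocks x %d trials, high feature '%s', seed %d\n",
    max(x$trials$block), max(x$trials$index_in_block),
    x$version$high_feature, x$seed
  ))
  print(x$trials, n = 5)
  invisible(x)
}

#' Compute trial payouts and feedback from responses
#'
#' Applies the SAT reward-scaling rule. On non-rewarded trials the payout is
#' 0 pence ("NoMoney") regardless of response speed. On rewarded trials:
#' no response, or a response after the probe disappeared, earns 5 pence
#' ("Missed"); a premature response (< 100 ms after probe onset) earns
#' 5 pence ("TooEarly"); a response within the probe window but no faster
#' than the practice mean RT earns 10 pence ("Hit"); a faster response earns
#' \deqn{X = 10 + 90 (\bar{RT} - RT) / (3\,SDF)}
#' pence, rounded to the nearest penny and capped at 100, with feedback
#' "Quick" when the advantage is under 1.5 SDF and "VeryQuick" otherwise.
#' So a response 1 SDF faster than the mean earns 40p, 2 SDFs 70p, and 3 or
#' more SDFs the 100p cap.
#'
#' @param trials A data frame with logical `rewarded` and numeric
#'   `probe_duration_ms` columns (e.g. `schedule$trials`), or a `sat_schedule`.
#' @param rt_ms Numeric vector of response times in milliseconds from probe
#'   onset (recycled if length 1); `NA` marks omissions.
#' @param calibration A `sat_calibration` object.
#' @return The trials as a tibble with columns `rt_ms`, `classification`
#'   (`"valid"`, `"premature"`, `"missed"`, `"omitted"`), `payout_pence`,
#'   and `feedback` (`"NoMoney"`, `"Missed"`, `"TooEarly"`, `"Hit"`,
#'   `"Quick"`, `"VeryQuick"`) appended.
#' @examples
#' cal <- calibration_profile(300, 20)
#' trials <- tibble::tibble(rewarded = TRUE, probe_duration_ms = 340)
#' compute_payout(trials, rt_ms = c(280, 260, 240), cal)
#' @export
compute_payout <- function(trials, rt_ms, calibration) {
  if (inherits(trials, "sat_schedule")) trials <- trials$trials
  stopifnot(is.data.frame(trials),
            all(c("rewarded", "probe_duration_ms") %in% names(trials)))
  if (!inherits(calibration, "sat_calibration")) {
    abort("`calibration` must be a sat_calibration")
  }
  if (any(rt_ms < 0, na.rm = TRUE)) abort("negative reaction times are invalid")
  n <- max(nrow(trials), length(rt_ms))
  if (nrow(trials) == 1 && length(rt_ms) > 1) {
    trials <- trials[rep(1, length(rt_ms)), ]
  }
  rt_ms <- rep_len(rt_ms, nrow(trials))

  mean_rt <- calibration$mean_rt_ms
  sdf <- calibration$sdf_ms

  classification <- dplyr::case_when(
    is.na(rt_ms) ~ "omitted",
    rt_ms < 100 ~ "premature",
    rt_ms > trials$probe_duration_ms ~ "missed",
    .default = "valid"
  )

  advantage <- mean_rt - rt_ms
  x_pence <- clamp(round(10 + 90 * advantage / (3 * sdf)), 10, 100)

  payout <- dplyr::case_when(
    !trials$rewarded ~ 0,
    classification %in% c("omitted", "missed", "premature") ~ 5,
    advantage <= 0 ~ 10,
    .default = x_pence
  )
  feedback <- dplyr::case_when(
    !trials$rewarded ~ "NoMoney",
    classification %in% c("omitted", "missed") ~ "Missed",
    classification == "premature" ~ "TooEarly",
    advantage <= 0 ~ "Hit",
    advantage < 1.5 * sdf ~ "Quick",
    .default = "VeryQuick"
  )

  out <- tibble::as_tibble(trials)
  out$rt_ms <- rt_ms
  out$classification <- classification
  out$payout_pence <- as.integer(payout)
  out$feedback <- feedback
  out
}
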