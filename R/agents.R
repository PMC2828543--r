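#' Parameters of a synthetic SAT subject
#'
#' The synthetic subject is a Rescorla-Wagner feature learner: it maintains
#' one weight per cue feature (blue, red, animal, object), values a compound
#' cue as the mean of its two feature weights, and after every trial moves
#' each presented feature's weight towards the observed reward by a fraction
#' `alpha` of the prediction error. Behaviour is generated from the learned
#' values: responses speed up linearly with cue value, and end-of-block
#' probability ratings track cue value. Aberrant salience is modelled as a
#' stable per-subject bias: one draw `delta ~ N(0, kappa)` splits the two
#' task-irrelevant feature values by `+delta/2` / `-delta/2` in the rating
#' stage, producing spurious value differences along the dimension whose two
#' levels are objectively rewarded at identical 50% rates.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param kappa Aberrant bias: standard deviation of the per-subject offset
#'   (value units, so 0.1 corresponds to a typical 10 mm rating split).
#' @param beta_rt Response speeding in ms per unit of cue value.
#' @param base_rt_ms Baseline response time (ms); `NULL` to use the
#'   subject's practice mean RT.
#' @param rt_noise_ms SD of Gaussian trial-to-trial RT noise (ms).
#' @param rating_noise_mm SD of Gaussian noise on the 100 mm VAS ratings.
#' @param omission_rate Probability of failing to respond on a trial.
#' @param premature_rate Probability of a premature response (< 100 ms after
#'   probe onset).
#' @return An `agent_params` object (a validated list).
#' @export
agent_params <- function(alpha = 0.2,
                         kappa = 0.1,
                         beta_rt = 40,
                         base_rt_ms = NULL,
                         rt_noise_ms = 30,
                         rating_noise_mm = 10,
                         omission_rate = 0.07,
                         premature_rate = 0.042) {
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  if (omission_rate < 0 || omission_rate > 1 ||
      premature_rate < 0 || premature_rate > 1) {
    abort("omission_rate and premature_rate must be probabilities")
  }
  if (kappa < 0 || rt_noise_ms < 0 || rating_noise_mm < 0) {
    abort("noise parameters must be non-negative")
  }
  structure(
    list(alpha = alpha, kappa = kappa, beta_rt = beta_rt,
         base_rt_ms = base_rt_ms, rt_noise_ms = rt_noise_ms,
         rating_noise_mm = rating_noise_mm, omission_rate = omission_rate,
         premature_rate = premature_rate),
    class = "agent_params"
  )
}

#' One Rescorla-Wagner update over cue features
#'
#' The compound cue's value is the mean of its two feature weights; both
#' presented features move by `alpha * (reward - value)`.
#'
#' @param weights Named numeric vector with elements `blue`, `red`, `animal`,
#'   `object`.
#' @param color,shape The presented cue's features.
#' @param reward 0 or 1.
#' @param alpha Learning rate in \[0, 1\].
#' @return The updated weight vector.
#' @examples
#' w <- c(blue = 0, red = 0, animal = 0, object = 0)
#' rw_update(w, "blue", "animal", reward = 1, alpha = 0.1)
#' @export
rw_update <- function(weights, color, shape, reward, alpha) {
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  stopifnot(all(c(color, shape) %in% names(weights)), all(is.finite(weights)))
  v <- mean(weights[c(color, shape)])
  pe <- reward - v
  weights[c(color, shape)] <- weights[c(color, shape)] + alpha * pe
  weights
}

# Value of each of the four cue types under a weight vector.
cue_type_values <- function(weights) {
  grid <- tidyr::expand_grid(color = c("blue", "red"),
                             shape = c("animal", "object"))
  grid$cue_type <- paste(grid$color, grid$shape, sep = "_")
  grid$value <- unname(weights[grid$color] + weights[grid$shape]) / 2
  grid
}

#' Simulate one subject's behaviour on a schedule
#'
#' Plays the Rescorla-Wagner agent through every trial of a schedule.
#' Per trial the response time is
#' `base_rt - beta_rt * V(cue) + N(0, rt_noise)`, truncated to the valid
#' response window (100 ms after probe onset up to probe offset) by
#' resampling (at most 100 draws, then clamping); omissions and premature
#' responses are injected at their configured rates. Weights update on the
#' trial's reward availability (feedback is delivered on every trial, so the
#' agent learns even when it misses). At the end of each block the agent
#' reports a 100 mm VAS probability rating per cue type:
#' `100 * (V_block + aberrant offset) + N(0, rating_noise)`, clamped to
#' \[0, 100\], where `V_block` is the cue type's learned value averaged over
#' the block's trials — a probability estimate integrates the whole block's
#' experience rather than the final trial's weight snapshot — and the offset
#' is `+delta/2` on cue types containing the first irrelevant-dimension
#' level and `-delta/2` on the others, `delta ~ N(0, kappa)` drawn once per
#' subject.
#'
#' @param schedule A [build_schedule()] result.
#' @param params An [agent_params()] object.
#' @param seed Integer seed; the same seed reproduces the log exactly.
#' @param subject_id Identifier stored in the log.
#' @return A `sat_subject` object: list with `subject_id`, `schedule`,
#'   `params`, `aberrant_offset` (the realised delta), `trials` (the schedule
#'   trials with response, classification, payout and feedback columns) and
#'   `ratings` (tibble: `subject`, `block`, `cue_type`, `color`, `shape`,
#'   `rating_mm`).
#' @export
emit_behavior <- function(schedule, params = agent_params(), seed,
                          subject_id = "sub-01") {
  if (!inherits(schedule, "sat_schedule")) abort("`schedule` must be a sat_schedule")
  if (!inherits(params, "agent_params")) params <- do.call(agent_params, params)
  cal <- schedule$calibration
  base_rt <- params$base_rt_ms %||% cal$mean_rt_ms

  trials <- schedule$trials
  n <- nrow(trials)
  weights <- c(blue = 0, red = 0, animal = 0, object = 0)
  irr_levels <- dimension_levels(schedule$version$irrelevant_dimension)

  rt <- numeric(n)
  ratings <- vector("list", max(trials$block))
  value_accum <- numeric(4)  # running sum of cue-type values within a block

  withr::with_seed(substream_seed(seed, paste0("behavior-", subject_id)), {
    delta <- rnorm(1, 0, params$kappa)
    kind <- runif(n)
    for (i in seq_len(n)) {
      v <- mean(weights[c(trials$color[i], trials$shape[i])])
      if (kind[i] < params$omission_rate) {
        rt[i] <- NA_real_
      } else if (kind[i] < params$omission_rate + params$premature_rate) {
        rt[i] <- runif(1, 0, 99)
      } else {
        mu <- base_rt - params$beta_rt * v
        lo <- 100
        hi <- trials$probe_duration_ms[i]
        r <- mu + rnorm(1, 0, params$rt_noise_ms)
        tries <- 1
        while ((r <= lo || r > hi) && tries < 100 && params$rt_noise_ms > 0) {
          r <- mu + rnorm(1, 0, params$rt_noise_ms)
          tries <- tries + 1
        }
        rt[i] <- clamp(r, lo + 1e-9, hi)
      }
      weights <- rw_update(weights, trials$color[i], trials$shape[i],
                           as.numeric(trials$rewarded[i]), params$alpha)
      value_accum <- value_accum + cue_type_values(weights)$value
      if (trials$index_in_block[i] == SAT_TRIALS_PER_BLOCK) {
        vals <- cue_type_values(weights)
        vals$value <- value_accum / SAT_TRIALS_PER_BLOCK
        value_accum <- numeric(4)
        irr_feature <- vals[[schedule$version$irrelevant_dimension]]
        offset <- ifelse(irr_feature == irr_levels[1], delta / 2, -delta / 2)
        vals$rating_mm <- clamp(
          100 * (vals$value + offset) + rnorm(4, 0, params$rating_noise_mm),
          0, 100
        )
        vals$block <- trials$block[i]
        vals$subject <- subject_id
        ratings[[trials$block[i]]] <-
          vals[, c("subject", "block", "cue_type", "color", "shape", "rating_mm")]
      }
    }
  })

  structure(
    list(
      subject_id = subject_id,
      schedule = schedule,
      params = params,
      aberrant_offset = delta,
      trials = compute_payout(trials, rt, cal),
      ratings = dplyr::bind_rows(ratings)
    ),
    class = "sat_subject"
  )
}

#' @export
print.sat_subject <- function(x, ...) {
  cat(sprintf(
    "<SAT subject %s> %d trials, %d block ratings, aberrant offset %.3f\n",
    x$subject_id, nrow(x$trials), nrow(x$ratings), x$aberrant_offset
  ))
  invisible(x)
}

#' Default population distributions for a simulated cohort
#'
#' Each subject draws a practice session (40 trials) whose location varies
#' across subjects, yielding realistic per-subject calibration profiles
#' (mean RT around 300 ms, SDF of the order of 15-20 ms).
#'
#' @param mean_rt_mean,mean_rt_sd Population mean and SD of subjects'
#'   typical practice RT (ms).
#' @param practice_sd Within-subject SD of practice RTs (ms).
#' @param n_practice Number of practice trials per subject.
#' @return A list of population settings for [simulate_cohort()].
#' @export
cohort_population <- function(mean_rt_mean = 300, mean_rt_sd = 25,
                              practice_sd = 40, n_practice = 40) {
  list(mean_rt_mean = mean_rt_mean, mean_rt_sd = mean_rt_sd,
       practice_sd = practice_sd, n_practice = n_practice)
}

#' Simulate a cohort of SAT subjects
#'
#' Generates `n` independent subjects. Each subject gets its own practice
#' session (hence calibration profile), task schedule (same task version,
#' subject-specific randomisation), and behaviour. Parameters may be shared
#' (`params` an [agent_params()]) or per-subject (a list of `n` such
#' objects, e.g. to grade the aberrant bias `kappa` across the cohort).
#'
#' @param n Number of subjects (>= 1); the study cohort size is 19.
#' @param params An [agent_params()] or a list of `n` of them.
#' @param master_seed Integer seed controlling the whole cohort.
#' @param version A [task_version()] (or feature name); applied to all
#'   subjects.
#' @param population Population settings from [cohort_population()].
#' @return A `sat_cohort`: list of `sat_subject` logs with attribute
#'   `master_seed`.
#' @examples
#' cohort <- simulate_cohort(3, agent_params(), master_seed = 1)
#' length(cohort)
#' @export
simulate_cohort <- function(n, params = agent_params(), master_seed,
                            version = task_version("blue"),
                            population = cohort_population()) {
  if (n < 1) abort("n must be at least 1")
  if (is.character(version)) version <- task_version(version)
  if (inherits(params, "agent_params")) {
    params <- rep(list(params), n)
  }
  if (length(params) != n) abort("`params` must have one element per subject")

  subjects <- purrr::map(seq_len(n), function(i) {
    sid <- sprintf("sub-%02d", i)
    s_seed <- substream_seed(master_seed, sid)
    practice <- withr::with_seed(
      substream_seed(s_seed, "practice"),
      rnorm(population$n_practice,
            rnorm(1, population$mean_rt_mean, population$mean_rt_sd),
            population$practice_sd)
    )
    practice <- pmax(practice, 120)
    cal <- calibrate(practice)
    sched <- build_schedule(version, substream_seed(s_seed, "schedule"), cal)
    emit_behavior(sched, params[[i]], seed = substream_seed(s_seed, "agent"),
                  subject_id = sid)
  })
  structure(subjects, class = "sat_cohort", master_seed = master_seed)
}

#' @export
print.sat_cohort <- function(x, ...) {
  cat(sprintf("<SAT cohort> %d subjects (master seed %s)\n",
              length(x), attr(x, "master_seed")))
  invisible(x)
}
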