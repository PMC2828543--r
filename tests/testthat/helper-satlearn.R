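# Shared fixture builders. Everything is generated in code at test time.

ref_calibration <- function() calibration_profile(300, 20)

# A hand-built subject log with fully controlled ratings and reaction times,
# for scoring tests that need exact arithmetic. `ratings_mm` is a 3 x 4
# matrix (blocks x cue types in the order blue_animal, blue_object,
# red_animal, red_object); `rt_by_type` likewise (recycled across blocks if
# a single row).
make_log <- function(ratings_mm,
                     rt_by_type = matrix(300, 1, 4),
                     version = task_version("blue"),
                     subject_id = "sub-hand") {
  cal <- ref_calibration()
  sched <- build_schedule(version, seed = 42, calibration = cal)
  trials <- sched$trials
  types <- c("blue_animal", "blue_object", "red_animal", "red_object")
  if (nrow(rt_by_type) == 1) rt_by_type <- rt_by_type[rep(1, 3), , drop = FALSE]
  rt <- rt_by_type[cbind(trials$block, match(trials$cue_type, types))]
  trials <- compute_payout(trials, rt, cal)
  ratings <- tidyr::expand_grid(block = 1:3, cue_type = types)
  ratings$subject <- subject_id
  ratings$color <- sub("_.*", "", ratings$cue_type)
  ratings$shape <- sub(".*_", "", ratings$cue_type)
  ratings$rating_mm <- as.vector(t(ratings_mm))
  structure(
    list(subject_id = subject_id, schedule = sched,
         params = agent_params(), aberrant_offset = 0,
         trials = trials,
         ratings = ratings[, c("subject", "block", "cue_type", "color",
                               "shape", "rating_mm")]),
    class = "sat_subject"
  )
}

# A single-run synthetic event stream long enough for a 500-scan session:
# two task blocks concatenated with the second block's onsets shifted by one
# block length. Returns the screened events plus the block-1 relabelling.
make_long_run_events <- function(seed = 1, params = agent_params()) {
  cal <- ref_calibration()
  sched <- build_schedule("blue", seed, cal)
  log <- emit_behavior(sched, params, seed = seed + 1)
  ev <- screen_events(log)
  block_len_s <- 64 * 9.25
  ev2 <- ev[ev$block == 2, ]
  ev2$cue_onset_s <- ev2$cue_onset_s + block_len_s
  ev2$outcome_onset_s <- ev2$outcome_onset_s + block_len_s
  out <- rbind(ev[ev$block == 1, ], ev2)
  out$block <- 1L
  list(events = out, log = log,
       relabel = subjective_relabel(log)[1, ],
       version = sched$version)
}

# Brute-force sphere membership: explicit triple loop over the whole grid.
brute_force_sphere <- function(center_mm, radius_mm, dim, spacing_mm,
                               origin_mm) {
  mask <- array(FALSE, dim = dim)
  for (i in seq_len(dim[1])) for (j in seq_len(dim[2])) for (k in seq_len(dim[3])) {
    p <- origin_mm + (c(i, j, k) - 1) * spacing_mm
    if (sum((p - center_mm)^2) <= radius_mm^2 + 1e-9) mask[i, j, k] <- TRUE
  }
  mask
}
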