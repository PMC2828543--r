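#' Write and read BIDS-style events files
#'
#' One tab-separated events file per block, with the standard `onset`,
#' `duration`, `trial_type` leading columns plus the SAT-specific columns
#' (`rewarded`, `probe_delay`, `probe_duration`, and — for behavioural logs —
#' `response_time`, `payout`, `feedback`). Onsets are cue onsets in seconds
#' from run start; duration is the modelled cue duration.
#'
#' @param log A `sat_subject` log or `sat_schedule`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are named
#'   `<prefix>_run-<block>_events.tsv`.
#' @return (Invisibly) the paths written.
#' @export
write_events_tsv <- function(log, dir, prefix = NULL) {
  if (inherits(log, "sat_schedule")) {
    trials <- log$trials
    prefix <- prefix %||% "schedule"
  } else if (inherits(log, "sat_subject")) {
    trials <- log$trials
    prefix <- prefix %||% log$subject_id
  } else {
    abort("`log` must be a sat_subject or sat_schedule")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  paths <- purrr::map_chr(sort(unique(trials$block)), function(b) {
    tb <- trials[trials$block == b, ]
    out <- tibble::tibble(
      onset = tb$cue_onset_s,
      duration = SAT_CUE_MODEL_DUR_S,
      trial_type = tb$cue_type,
      color = tb$color,
      shape = tb$shape,
      relevant_level = tb$relevant_level,
      rewarded = tb$rewarded,
      probe_delay = tb$probe_delay_s,
      probe_duration = tb$probe_duration_ms
    )
    if ("rt_ms" %in% names(tb)) {
      out$response_time <- tb$rt_ms
      out$classification <- tb$classification
      out$payout <- tb$payout_pence
      out$feedback <- tb$feedback
    }
    path <- file.path(dir, sprintf("%s_run-%02d_events.tsv", prefix, b))
    readr::write_tsv(out, path)
    path
  })
  invisible(paths)
}

#' @rdname write_events_tsv
#' @param paths Event file paths (one per block, in block order).
#' @return `read_events_tsv()`: a single tibble with a `block` column.
#' @export
read_events_tsv <- function(paths) {
  purrr::imap_dfr(paths, function(p, i) {
    ev <- readr::read_tsv(p, show_col_types = FALSE)
    ev$block <- i
    ev
  })
}

#' Write and read the end-of-block VAS ratings table
#'
#' @param log A `sat_subject` log (or its `ratings` tibble).
#' @param path Output CSV path.
#' @return (Invisibly) `path`; `read_ratings_csv()` returns the tibble.
#' @export
write_ratings_csv <- function(log, path) {
  ratings <- if (inherits(log, "sat_subject")) log$ratings else log
  readr::write_csv(
    ratings[, c("subject", "block", "cue_type", "color", "shape", "rating_mm")],
    path
  )
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write and read a two-column calibration file
#'
#' Plain key/value text with keys `mean_rt_ms` and `sdf_ms`.
#'
#' @param calibration A `sat_calibration`.
#' @param path File path.
#' @return (Invisibly) `path`; the reader returns a `sat_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  writeLines(c(
    paste("mean_rt_ms", format(calibration$mean_rt_ms, digits = 15)),
    paste("sdf_ms", format(calibration$sdf_ms, digits = 15))
  ), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  kv <- utils::read.table(path, col.names = c("key", "value"))
  vals <- stats::setNames(kv$value, kv$key)
  calibration_profile(as.numeric(vals[["mean_rt_ms"]]),
                      as.numeric(vals[["sdf_ms"]]))
}

#' Write a per-voxel map as a NIfTI volume
#'
#' Reshapes a voxel vector (column-major grid order) to the grid and writes
#' a NIfTI file with isotropic spacing.
#'
#' @param values Numeric vector, one value per voxel.
#' @param dim Length-3 grid dimensions.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param spacing_mm Isotropic voxel size.
#' @return (Invisibly) `path`.
#' @export
write_nifti_map <- function(values, dim, path, spacing_mm = 3) {
  stopifnot(length(values) == prod(dim))
  img <- RNifti::asNifti(array(values, dim = dim),
                         pixdim = rep(spacing_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_map
#' @param path Path of a NIfTI volume.
#' @return `read_nifti_map()`: the image as a numeric array.
#' @export
read_nifti_map <- function(path) {
  as.array(RNifti::readNifti(path))
}
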