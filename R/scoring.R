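#' Binary entropy of a cue's reward outcome
#'
#' The uncertainty (in nats) of a Bernoulli reward outcome with probability
#' `p`: `-(p log p + (1 - p) log(1 - p))`, with `0 log 0 = 0`. The SAT's
#' task-relevant cue features (87.5% and 12.5% reward) both carry entropy
#' 0.377; the task-irrelevant features (50%) carry the maximal 0.693.
#'
#' @param p Probability (vectorised) in \[0, 1\].
#' @return Entropy in nats.
#' @examples
#' outcome_entropy(c(0.875, 0.5))
#' @export
outcome_entropy <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p must lie in [0, 1]")
  term <- function(q) ifelse(q == 0, 0, q * log(q))
  -(term(p) + term(1 - p))
}

# Mean rating of a feature level = mean over the two cue types containing it
# (the VAS probes cue types, not features).
level_ratings <- function(ratings, dimension) {
  ratings |>
    dplyr::group_by(.data$block, level = .data[[dimension]]) |>
    dplyr::summarise(rating_mm = mean(.data$rating_mm), .groups = "drop")
}

#' Subjective relabelling of the task-irrelevant dimension
#'
#' For each block, the irrelevant-dimension level with the higher mean VAS
#' rating (averaged over the two cue types containing it) is labelled
#' subjectively "high-probability", the other "low"; this per-block mapping
#' defines the aberrant reward-prediction contrast. Exact ties are broken
#' deterministically in canonical level order (animal before object, blue
#' before red) and flagged.
#'
#' @param log A `sat_subject` log (or a ratings tibble with `block`, colour
#'   and shape columns and `rating_mm`, plus a `dimension` argument).
#' @param dimension The irrelevant dimension; inferred from the log's task
#'   version when a log is supplied.
#' @return A tibble with one row per block: `block`, `subjective_high`,
#'   `subjective_low`, `tie`.
#' @export
subjective_relabel <- function(log, dimension = NULL) {
  if (inherits(log, "sat_subject")) {
    dimension <- log$schedule$version$irrelevant_dimension
    ratings <- log$ratings
  } else {
    ratings <- log
    if (is.null(dimension)) abort("`dimension` is required for raw ratings")
  }
  canonical <- dimension_levels(dimension)
  lr <- level_ratings(ratings, dimension)
  lr |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(
      subjective_high = {
        r <- stats::setNames(.data$rating_mm, .data$level)[canonical]
        canonical[which.max(r)]  # which.max takes the first on ties
      },
      tie = abs(diff(.data$rating_mm)) < .Machine$double.eps^0.5,
      .groups = "drop"
    ) |>
    dplyr::mutate(subjective_low = ifelse(.data$subjective_high == canonical[1],
                                          canonical[2], canonical[1]),
                  .after = "subjective_high")
}

#' Score one subject's learning measures
#'
#' Computes, per block, the four SAT reward-learning outcome measures:
#' \describe{
#'   \item{adaptive_explicit_mm}{VAS rating for the high-probability
#'     relevant feature minus the low-probability one.}
#'   \item{aberrant_explicit_mm}{Absolute VAS rating difference between the
#'     two task-irrelevant levels (both rewarded at 50%).}
#'   \item{adaptive_implicit_ms}{Mean RT on low-probability trials minus
#'     high-probability trials (positive = adaptive speeding), valid
#'     responses only.}
#'   \item{aberrant_implicit_ms}{Absolute mean-RT difference between the two
#'     irrelevant levels, valid responses only.}
#' }
#' Feature-level ratings are means over the two cue types containing the
#' feature. Implicit measures use trials classified `"valid"` only
#' (omissions, premature and late responses carry no meaningful RT); a block
#' condition with no valid RTs yields `NA`. The per-block subjective
#' relabelling direction is appended.
#'
#' @param log A `sat_subject` log.
#' @return A tibble with one row per block: `subject`, `block`, the four
#'   measures, `relabel_high`, `relabel_tie`.
#' @export
score_subject <- function(log) {
  if (!inherits(log, "sat_subject")) abort("`log` must be a sat_subject")
  version <- log$schedule$version
  if (!all(1:3 %in% log$ratings$block) || nrow(log$ratings) < 12) {
    abort("ratings for all 4 cue types in each block are required")
  }

  rel <- version$relevant_dimension
  irr <- version$irrelevant_dimension
  irr_lv <- dimension_levels(irr)

  rel_ratings <- level_ratings(log$ratings, rel) |>
    dplyr::mutate(level = ifelse(.data$level == version$high_feature,
                                 "high", "low")) |>
    tidyr::pivot_wider(names_from = "level", values_from = "rating_mm")
  irr_ratings <- level_ratings(log$ratings, irr) |>
    tidyr::pivot_wider(names_from = "level", values_from = "rating_mm")

  valid <- dplyr::filter(log$trials, .data$classification == "valid")
  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  rel_rt <- valid |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(
      rt_high = mean_or_na(.data$rt_ms[.data$relevant_level == "high"]),
      rt_low = mean_or_na(.data$rt_ms[.data$relevant_level == "low"]),
      rt_irr1 = mean_or_na(.data$rt_ms[.data[[irr]] == irr_lv[1]]),
      rt_irr2 = mean_or_na(.data$rt_ms[.data[[irr]] == irr_lv[2]]),
      .groups = "drop"
    )

  relabel <- subjective_relabel(log)

  tibble::tibble(block = 1:3) |>
    dplyr::left_join(rel_ratings, by = "block") |>
    dplyr::left_join(irr_ratings, by = "block") |>
    dplyr::left_join(rel_rt, by = "block") |>
    dplyr::left_join(relabel, by = "block") |>
    dplyr::transmute(
      subject = log$subject_id,
      block = .data$block,
      adaptive_explicit_mm = .data$high - .data$low,
      aberrant_explicit_mm = abs(.data[[irr_lv[1]]] - .data[[irr_lv[2]]]),
      adaptive_implicit_ms = .data$rt_low - .data$rt_high,
      aberrant_implicit_ms = abs(.data$rt_irr1 - .data$rt_irr2),
      relabel_high = .data$subjective_high,
      relabel_tie = .data$tie
    )
}

#' Score every subject in a cohort
#'
#' @param cohort A `sat_cohort` (or plain list of `sat_subject` logs).
#' @return A tibble of per-block measures, one row per subject x block.
#' @export
score_cohort <- function(cohort) {
  purrr::map(cohort, score_subject) |> dplyr::bind_rows()
}

#' Average per-block measures over blocks
#'
#' The group analyses use each subject's learning measures averaged over the
#' three blocks.
#'
#' @param measures Per-block measures from [score_subject()]/[score_cohort()].
#' @return One row per subject with block-averaged measures.
#' @export
summarise_measures <- function(measures) {
  measures |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(dplyr::across(
      c("adaptive_explicit_mm", "aberrant_explicit_mm",
        "adaptive_implicit_ms", "aberrant_implicit_ms"),
      ~ mean(.x, na.rm = TRUE)
    ), .groups = "drop")
}

#' Exclude outlying subjects by a leave-one-out z criterion
#'
#' A subject is excluded when its value lies more than `threshold_sd`
#' standard deviations from the mean of the *remaining* subjects, so a
#' gross outlier cannot mask itself by inflating the pooled SD. Typically
#' applied to the implicit adaptive measure.
#'
#' @param data A data frame with one row per subject.
#' @param value Column to screen (tidy-eval).
#' @param threshold_sd Exclusion threshold in SDs (default 3.5).
#' @return `data` with `loo_z` and `excluded` columns appended.
#' @examples
#' d <- tibble::tibble(subject = 1:5, m = c(6, 7, 6.5, 6.2, -40))
#' exclude_outliers(d, m)
#' @export
exclude_outliers <- function(data, value, threshold_sd = 3.5) {
  if (nrow(data) < 3) abort("outlier screening needs at least 3 subjects")
  x <- dplyr::pull(data, {{ value }})
  loo_z <- vapply(seq_along(x), function(i) {
    rest <- x[-i]
    (x[i] - mean(rest)) / sd(rest)
  }, numeric(1))
  data$loo_z <- loo_z
  data$excluded <- abs(loo_z) > threshold_sd
  data
}

#' Summarise a subject's earnings and error counts
#'
#' @param log A `sat_subject` log.
#' @return A `sat_earnings` list of tibbles: `by_condition` (mean payout per
#'   *rewarded* trial split by relevant-dimension probability and by
#'   irrelevant level, per block), `by_block` (total pence per block), and
#'   `errors` (premature and omission counts per block and cue type).
#' @export
summarize_earnings <- function(log) {
  if (!inherits(log, "sat_subject")) abort("`log` must be a sat_subject")
  trials <- log$trials
  irr <- log$schedule$version$irrelevant_dimension
  rewarded <- dplyr::filter(trials, .data$rewarded)

  by_probability <- rewarded |>
    dplyr::group_by(.data$block, condition = paste0("relevant_", .data$relevant_level)) |>
    dplyr::summarise(n_rewarded = dplyr::n(),
                     mean_payout_pence = mean(.data$payout_pence),
                     .groups = "drop")
  by_irrelevant <- rewarded |>
    dplyr::group_by(.data$block, condition = paste0("irrelevant_", .data[[irr]])) |>
    dplyr::summarise(n_rewarded = dplyr::n(),
                     mean_payout_pence = mean(.data$payout_pence),
                     .groups = "drop")

  by_block <- trials |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(total_pence = sum(.data$payout_pence), .groups = "drop")

  errors <- trials |>
    dplyr::group_by(.data$block, .data$cue_type) |>
    dplyr::summarise(
      premature = sum(.data$classification == "premature"),
      omissions = sum(.data$classification == "omitted"),
      .groups = "drop"
    )

  structure(
    list(by_condition = dplyr::bind_rows(by_probability, by_irrelevant),
         by_block = by_block, errors = errors),
    class = "sat_earnings"
  )
}

#' @export
print.sat_earnings <- function(x, ...) {
  cat("<SAT earnings>\nPer-block totals (pence):\n")
  print(x$by_block)
  cat("Mean payout per rewarded trial by condition:\n")
  print(x$by_condition, n = 6)
  invisible(x)
}

#' Cohort-level inferential statistics on the learning measures
#'
#' Computes, for each of the four learning measures: a one-sample t-test of
#' the block-averaged measure against zero (the test of whether the
#' contingencies were acquired), Pearson correlations between all measure
#' pairs, and paired t-tests between blocks (learning progression). Measures
#' with zero variance are flagged and skipped.
#'
#' @param measures Per-block measures from [score_cohort()].
#' @return A `sat_cohort_stats` list with tibbles `tests`, `correlations`,
#'   `block_contrasts`.
#' @export
cohort_stats <- function(measures) {
  mcols <- c("adaptive_explicit_mm", "aberrant_explicit_mm",
             "adaptive_implicit_ms", "aberrant_implicit_ms")
  avg <- summarise_measures(measures)
  if (nrow(avg) < 3) abort("cohort statistics need at least 3 subjects")

  # t.test itself refuses data that are constant to rounding error; treat
  # that case as degenerate rather than an error
  near_constant <- function(x) sd(x) <= max(abs(mean(x)), 1) * 1e-10

  tests <- purrr::map_dfr(mcols, function(m) {
    x <- avg[[m]][is.finite(avg[[m]])]
    if (length(x) < 3 || near_constant(x)) {
      return(tibble::tibble(measure = m, n = length(x), mean = mean(x),
                            sd = sd(x), t = NA_real_, df = NA_real_,
                            p = NA_real_, degenerate = TRUE))
    }
    tt <- t.test(x, mu = 0)
    tibble::tibble(measure = m, n = length(x), mean = mean(x), sd = sd(x),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, degenerate = FALSE)
  })

  pairs <- utils::combn(mcols, 2, simplify = FALSE)
  correlations <- purrr::map_dfr(pairs, function(pr) {
    x <- avg[[pr[1]]]; y <- avg[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(measure_1 = pr[1], measure_2 = pr[2],
                            r = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    ct <- cor.test(x[ok], y[ok])
    tibble::tibble(measure_1 = pr[1], measure_2 = pr[2],
                   r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
  })

  block_pairs <- list(c(1, 2), c(2, 3), c(1, 3))
  block_contrasts <- purrr::map_dfr(mcols, function(m) {
    wide <- measures |>
      dplyr::select("subject", "block", dplyr::all_of(m)) |>
      tidyr::pivot_wider(names_from = "block", values_from = dplyr::all_of(m))
    purrr::map_dfr(block_pairs, function(bp) {
      a <- wide[[as.character(bp[1])]]; b <- wide[[as.character(bp[2])]]
      ok <- is.finite(a) & is.finite(b)
      d <- a[ok] - b[ok]
      if (length(d) < 3 || near_constant(d)) {
        return(tibble::tibble(measure = m, block_a = bp[1], block_b = bp[2],
                              t = NA_real_, df = NA_real_, p = NA_real_,
                              degenerate = TRUE))
      }
      tt <- t.test(d, mu = 0)
      tibble::tibble(measure = m, block_a = bp[1], block_b = bp[2],
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value, degenerate = FALSE)
    })
  })

  structure(
    list(tests = tests, correlations = correlations,
         block_contrasts = block_contrasts),
    class = "sat_cohort_stats"
  )
}

#' @export
print.sat_cohort_stats <- function(x, ...) {
  cat("<SAT cohort statistics>\nOne-sample t-tests against zero:\n")
  print(x$tests)
  cat("Measure correlations:\n")
  print(x$correlations)
  invisible(x)
}
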