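#' Plot the payout rule
#'
#' The reward-scaling curve for a calibration profile: payout in pence as a
#' function of response time on a rewarded trial, showing the 5p
#' missed/premature floor, the 10p "Hit" plateau, the linear scaling region
#' and the 100p cap.
#'
#' @param calibration A `sat_calibration`.
#' @param probe_duration_ms Probe duration assumed for the missed boundary.
#' @return A ggplot object.
#' @export
plot_payout_curve <- function(calibration,
                              probe_duration_ms = calibration$mean_rt_ms +
                                2 * calibration$sdf_ms) {
  rt <- seq(0, probe_duration_ms + 50, by = 1)
  trials <- tibble::tibble(rewarded = TRUE, probe_duration_ms = probe_duration_ms)
  res <- compute_payout(trials, rt, calibration)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$rt_ms, y = .data$payout_pence,
                                    colour = .data$feedback)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "response time after probe onset (ms)",
                  y = "payout (pence)", colour = "feedback") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sat_schedule <- function(object, ...) {
  trials <- object$trials
  ggplot2::ggplot(trials,
                  ggplot2::aes(x = .data$index_in_block, y = .data$cue_type,
                               fill = .data$rewarded)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::facet_wrap(~block, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "trial within block", y = NULL, fill = "rewarded") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sat_design <- function(object, ...) {
  df <- tibble::as_tibble(scale(object$X), .name_repair = "minimal")
  names(df) <- colnames(object$X)
  df$scan <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, -"scan", names_to = "column")
  long$column <- factor(long$column, levels = colnames(object$X))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$scan,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = "scan", fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Plot cohort learning measures
#'
#' One panel per measure, per-block subject trajectories with the cohort
#' mean overlaid.
#'
#' @param measures Per-block measures from [score_cohort()].
#' @return A ggplot object.
#' @export
plot_learning_measures <- function(measures) {
  long <- measures |>
    tidyr::pivot_longer(
      c("adaptive_explicit_mm", "aberrant_explicit_mm",
        "adaptive_implicit_ms", "aberrant_implicit_ms"),
      names_to = "measure"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$block, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject), alpha = 0.3) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "red",
                          linewidth = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "block", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sat_group <- function(object, ...) {
  st <- object$stats
  yvar <- if (object$has_covariate) "covariate_t" else "mean_t"
  ggplot2::ggplot(st, ggplot2::aes(x = .data$voxel, y = .data[[yvar]])) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "voxel", y = paste(yvar, "statistic")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sat_permutation <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(max_t = object$max_null),
                  ggplot2::aes(x = .data$max_t)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = max(abs(object$observed_t)),
                        colour = "red") +
    ggplot2::labs(x = "max |t| under permutation", y = "count") +
    ggplot2::theme_minimal()
}
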