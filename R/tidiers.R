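#' Tidy and glance methods
#'
#' Broom-style accessors for the package's fitted objects: `tidy()` returns
#' one row per estimated quantity, `glance()` a one-row model summary.
#'
#' @param x A fitted object (`sat_glm`, `sat_group`, `sat_permutation`,
#'   `sat_cohort_stats`).
#' @param ... Unused.
#' @return A tibble.
#' @name satlearn-tidiers
NULL

#' @rdname satlearn-tidiers
#' @export
tidy.sat_glm <- function(x, ...) {
  tibble::as_tibble(x$betas, rownames = "term") |>
    tidyr::pivot_longer(-"term", names_to = "voxel", values_to = "estimate") |>
    dplyr::mutate(voxel = match(.data$voxel, unique(.data$voxel)))
}

#' @rdname satlearn-tidiers
#' @export
glance.sat_glm <- function(x, ...) {
  tibble::tibble(
    n_scans = if (!is.null(x$design)) x$design$n_scans else NA_integer_,
    n_columns = nrow(x$betas),
    n_voxels = ncol(x$betas),
    rho = x$rho,
    df_residual = x$df_residual
  )
}

#' @rdname satlearn-tidiers
#' @export
tidy.sat_group <- function(x, ...) x$stats

#' @rdname satlearn-tidiers
#' @export
glance.sat_group <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, n_voxels = nrow(x$stats),
                 has_covariate = x$has_covariate)
}

#' @rdname satlearn-tidiers
#' @export
tidy.sat_permutation <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$observed_t), t = x$observed_t,
                 p_corrected = x$p_corrected)
}

#' @rdname satlearn-tidiers
#' @export
glance.sat_permutation <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, n_perm = x$n_perm,
                 n_voxels = length(x$observed_t),
                 n_significant_05 = sum(x$p_corrected < 0.05))
}

#' @rdname satlearn-tidiers
#' @export
tidy.sat_cohort_stats <- function(x, ...) x$tests

#' @rdname satlearn-tidiers
#' @export
glance.sat_cohort_stats <- function(x, ...) {
  tibble::tibble(n_measures = nrow(x$tests),
                 n_correlations = nrow(x$correlations),
                 n_block_contrasts = nrow(x$block_contrasts))
}
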