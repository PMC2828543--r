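#' Group-level one-sample test with a learning-measure covariate
#'
#' The summary-statistics random-effects model: each subject contributes one
#' contrast map, and at every voxel the maps are regressed on an intercept
#' plus a mean-centred covariate (a block-averaged learning measure). The
#' intercept t-statistic tests the group mean effect (the plain one-sample
#' t-test); the covariate t-statistic tests inter-individual association,
#' and the corresponding Pearson correlation is reported alongside it
#' (`t^2 = r^2 (n-2) / (1-r^2)` holds exactly).
#'
#' @param maps Numeric matrix, subjects x voxels (or a list of per-subject
#'   vectors).
#' @param covariate Numeric vector, one value per subject, or `NULL` for a
#'   plain one-sample test.
#' @return A `sat_group` object with per-voxel tibble `stats` (columns
#'   `voxel`, `mean_t`, `mean_se`, `covariate_slope`, `covariate_t`,
#'   `covariate_r`, plus `degenerate` flags) and fields `n`, `df`.
#' @export
group_fit <- function(maps, covariate = NULL) {
  if (is.list(maps) && !is.matrix(maps)) maps <- do.call(rbind, maps)
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 3) abort("group analysis needs at least 3 subjects")

  has_cov <- !is.null(covariate)
  if (has_cov) {
    if (length(covariate) != n) abort("covariate length must equal the number of subjects")
    if (sd(covariate) == 0) {
      warn("covariate is constant; covariate tests skipped")
      has_cov <- FALSE
    }
  }

  if (has_cov) {
    c0 <- covariate - mean(covariate)
    X <- cbind(intercept = 1, covariate = c0)
  } else {
    X <- cbind(intercept = rep(1, n))
  }
  XtXi <- chol2inv(chol(crossprod(X)))
  beta <- XtXi %*% crossprod(X, maps)
  resid <- maps - X %*% beta
  df <- n - ncol(X)
  sigma2 <- colSums(resid^2) / df
  # residual variance at rounding-noise level relative to the data scale
  degenerate <- sigma2 <= (colMeans(maps^2) + .Machine$double.xmin) * 1e-20

  mean_se <- sqrt(XtXi[1, 1] * sigma2)
  mean_t <- beta[1, ] / mean_se
  mean_t[degenerate] <- ifelse(beta[1, degenerate] == 0, 0,
                               Inf * sign(beta[1, degenerate]))

  stats <- tibble::tibble(
    voxel = seq_len(ncol(maps)),
    mean_effect = beta[1, ],
    mean_se = mean_se,
    mean_t = mean_t,
    degenerate = degenerate
  )
  if (has_cov) {
    slope_se <- sqrt(XtXi[2, 2] * sigma2)
    cov_t <- beta[2, ] / slope_se
    cov_t[degenerate & abs(beta[2, ]) < 1e-12] <- 0
    r <- suppressWarnings(as.numeric(cor(covariate, maps)))
    r[!is.finite(r)] <- 0
    stats$covariate_slope <- beta[2, ]
    stats$covariate_se <- slope_se
    stats$covariate_t <- cov_t
    stats$covariate_r <- r
  }

  structure(
    list(stats = stats, n = n, df = df, has_covariate = has_cov,
         maps = maps, covariate = if (has_cov) covariate else NULL),
    class = "sat_group"
  )
}

#' @export
print.sat_group <- function(x, ...) {
  cat(sprintf("<SAT group analysis> n = %d subjects, %d voxels%s\n",
              x$n, nrow(x$stats),
              if (x$has_covariate) ", with covariate" else ""))
  print(x$stats, n = 5)
  invisible(x)
}

#' Spherical volume-of-interest mask
#'
#' Marks every voxel whose centre lies within Euclidean distance `radius_mm`
#' of a centre given in world (mm) coordinates. The grid maps voxel indices
#' `(i, j, k)` (1-based) to mm via `origin_mm + (index - 1) * spacing_mm`
#' (isotropic spacing, axis-aligned — the convention of analyses on
#' MNI-space images).
#'
#' @param center_mm Length-3 numeric, sphere centre in mm.
#' @param radius_mm Sphere radius in mm (study default 8).
#' @param dim Length-3 integer grid dimensions.
#' @param spacing_mm Isotropic voxel size in mm (study grid: 3).
#' @param origin_mm mm coordinates of voxel (1, 1, 1).
#' @return A logical array of dimension `dim`; errors if no voxel falls
#'   inside the sphere.
#' @examples
#' m <- sphere_mask(c(0, 0, 0), 8, dim = c(11, 11, 11),
#'                  spacing_mm = 3, origin_mm = c(-15, -15, -15))
#' sum(m)
#' @export
sphere_mask <- function(center_mm, radius_mm = 8, dim, spacing_mm = 3,
                        origin_mm = c(0, 0, 0)) {
  stopifnot(length(center_mm) == 3, length(dim) == 3)
  if (radius_mm < 0) abort("radius must be non-negative")
  ax <- lapply(1:3, function(a) origin_mm[a] + (seq_len(dim[a]) - 1) * spacing_mm)
  d2 <- outer(
    outer((ax[[1]] - center_mm[1])^2, (ax[[2]] - center_mm[2])^2, `+`),
    (ax[[3]] - center_mm[3])^2, `+`
  )
  mask <- array(d2 <= radius_mm^2 + 1e-9, dim = dim)
  if (!any(mask)) abort("sphere mask is empty on this grid")
  mask
}

#' Mean contrast value within volumes of interest
#'
#' @param maps Subjects x voxels matrix whose voxel order is the
#'   column-major order of the grid.
#' @param vois Named list of logical masks from [sphere_mask()].
#' @return A tibble: `subject`, `voi`, `mean_contrast`.
#' @export
voi_summary <- function(maps, vois) {
  purrr::imap_dfr(vois, function(mask, nm) {
    tibble::tibble(
      subject = seq_len(nrow(maps)),
      voi = nm,
      mean_contrast = rowMeans(maps[, as.vector(mask), drop = FALSE])
    )
  })
}

#' Familywise-error-corrected p-values by max-statistic permutation
#'
#' Voxel-level familywise error control without distributional or smoothness
#' assumptions: the null distribution of the *maximum* absolute t-statistic
#' over voxels is built by permutation, and each voxel's corrected p is the
#' rank of its observed |t| within that distribution. For the group mean
#' effect the permutation scheme is subject-wise sign flipping (exact under
#' symmetric errors); for the covariate effect it is random reshuffling of
#' the covariate across subjects.
#'
#' @param maps Subjects x voxels matrix.
#' @param covariate Per-subject covariate (required when
#'   `statistic = "covariate"`).
#' @param statistic `"mean"` or `"covariate"`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return A `sat_permutation` list: `observed_t`, `p_corrected` (per
#'   voxel), `max_null` (the permutation distribution), `statistic`,
#'   `n_perm`.
#' @export
permutation_correct <- function(maps, covariate = NULL,
                                statistic = c("mean", "covariate"),
                                n_perm = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n_perm < 100) abort("at least 100 permutations are required")
  if (statistic == "covariate" && is.null(covariate)) {
    abort("a covariate is required for the covariate statistic")
  }

  t_mean <- function(M) {
    m <- colMeans(M)
    s <- sqrt((colSums(M^2) - n * m^2) / (n - 1))
    m / (s / sqrt(n))
  }
  t_cov <- function(M, cv) {
    r <- suppressWarnings(as.numeric(cor(cv, M)))
    r[!is.finite(r)] <- 0
    r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  }

  if (statistic == "mean") {
    observed <- t_mean(maps)
    max_null <- withr::with_seed(substream_seed(seed, "signflip"), {
      vapply(seq_len(n_perm), function(p) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        max(abs(t_mean(maps * s)))
      }, numeric(1))
    })
  } else {
    observed <- t_cov(maps, covariate)
    max_null <- withr::with_seed(substream_seed(seed, "shuffle"), {
      vapply(seq_len(n_perm), function(p) {
        max(abs(t_cov(maps, sample(covariate))))
      }, numeric(1))
    })
  }

  p_corrected <- vapply(abs(observed), function(tv) {
    (1 + sum(max_null >= tv)) / (n_perm + 1)
  }, numeric(1))

  structure(
    list(observed_t = observed, p_corrected = p_corrected,
         max_null = max_null, statistic = statistic, n_perm = n_perm),
    class = "sat_permutation"
  )
}

#' @export
print.sat_permutation <- function(x, ...) {
  cat(sprintf(
    "<SAT permutation correction> %s statistic, %d permutations, %d voxels, min corrected p = %.4f\n",
    x$statistic, x$n_perm, length(x$observed_t), min(x$p_corrected)
  ))
  invisible(x)
}
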