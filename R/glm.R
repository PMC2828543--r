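#' Screen a subject log into GLM events
#'
#' Converts a behavioural log into the event set the first-level model uses.
#' Cue events (duration 2 s from cue onset) are *excluded* when the subject
#' failed to respond at all — attention cannot be assumed — or responded
#' extremely prematurely, within 1250 ms of cue onset, to avoid contaminating
#' cue-locked responses with movement. Outcome events (duration 1.5 s from
#' feedback onset) are retained for every trial, because the feedback tone
#' conveys the reward magnitude regardless of where the subject is looking;
#' the magnitude modulator is the trial payout in pence (0 on non-rewarded
#' trials).
#'
#' @param log A `sat_subject` log.
#' @return A tibble with one row per trial: `block`, `cue_type`,
#'   `cue_onset_s`, `cue_duration_s`, `cue_included`, `outcome_onset_s`,
#'   `outcome_duration_s`, `magnitude_pence`.
#' @export
screen_events <- function(log) {
  if (!inherits(log, "sat_subject")) abort("`log` must be a sat_subject")
  trials <- log$trials
  # response latency measured from cue onset
  resp_after_cue_ms <- (trials$probe_onset_s - trials$cue_onset_s) * 1000 +
    trials$rt_ms
  tibble::tibble(
    block = trials$block,
    cue_type = trials$cue_type,
    relevant_level = trials$relevant_level,
    color = trials$color,
    shape = trials$shape,
    cue_onset_s = trials$cue_onset_s,
    cue_duration_s = SAT_CUE_MODEL_DUR_S,
    cue_included = !is.na(trials$rt_ms) & resp_after_cue_ms >= 1250,
    outcome_onset_s = trials$probe_onset_s + SAT_FEEDBACK_DELAY_S,
    outcome_duration_s = SAT_FEEDBACK_DUR_S,
    magnitude_pence = trials$payout_pence
  )
}

#' Haemodynamic response basis set
#'
#' The canonical double-gamma haemodynamic response function (response peak
#' at 6 s, undershoot peaking at 16 s, response/undershoot amplitude ratio
#' 6, support 0-32 s), normalised to unit peak, plus two derivative terms
#' that absorb inter-regional variability in response shape: the temporal
#' derivative (finite difference with respect to a 1 s onset shift) and the
#' dispersion derivative (finite difference with respect to a 1% change in
#' the response-gamma dispersion).
#'
#' @param resolution_s Sampling interval of the returned curves (s).
#' @param length_s Support of the response (s).
#' @return A tibble with columns `time_s`, `canonical`, `temporal`,
#'   `dispersion`.
#' @examples
#' basis <- hrf_basis(0.1)
#' basis$time_s[which.max(basis$canonical)]  # ~5 s (mode of Gamma(6, 1))
#' @export
hrf_basis <- function(resolution_s, length_s = 32) {
  if (resolution_s <= 0) abort("resolution must be positive")
  tt <- seq(0, length_s, by = resolution_s)
  f <- function(t, disp = 1) {
    ifelse(t < 0, 0,
           dgamma(t, shape = 6 / disp, scale = disp) -
             dgamma(t, shape = 16, scale = 1) / 6)
  }
  scale <- max(f(tt))
  canonical <- f(tt) / scale
  temporal <- (f(tt) - f(tt - 1)) / scale          # 1 s onset shift
  dispersion <- (f(tt) - f(tt, disp = 1.01)) / 0.01 / scale
  tibble::tibble(time_s = tt, canonical = canonical, temporal = temporal,
                 dispersion = dispersion)
}

# Discrete cosine drift basis with high-pass cutoff (s); k = 1..K columns.
cosine_drifts <- function(n_scans, tr, cutoff_s = 128) {
  k_max <- floor(2 * n_scans * tr / cutoff_s)
  if (k_max < 1) return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  i <- seq_len(n_scans) - 1
  m <- sapply(seq_len(k_max), function(k) {
    sqrt(2 / n_scans) * cos(pi * (2 * i + 1) * k / (2 * n_scans))
  })
  colnames(m) <- paste0("drift_", seq_len(k_max))
  m
}

#' Build a first-level design matrix for one run
#'
#' Constructs the run's design at TR resolution: one regressor set per cue
#' type (4 conditions; excluded cue events contribute nothing), one for the
#' outcome, and one for the outcome parametrically modulated by reward
#' magnitude (mean-centred over all outcome events before convolution, to
#' decorrelate it from the unmodulated outcome regressor). Each condition's
#' boxcar is built on a microtime grid (16 bins per TR), convolved with the
#' three-function haemodynamic basis from [hrf_basis()], and sampled at scan
#' onsets. Discrete cosine drift terms up to the 1/128 Hz cutoff and a
#' trailing intercept complete the matrix, giving
#' `6 conditions x 3 bases + k drifts + 1` columns.
#'
#' @param events An event tibble from [screen_events()] (one block/run).
#' @param n_scans Number of volumes in the run.
#' @param tr Repetition time (s); the acquisition used 2.73 s.
#' @param hp_cutoff_s High-pass drift cutoff (s).
#' @param microtime_bins Convolution oversampling per TR.
#' @return A `sat_design` object: list with `X` (n_scans x columns matrix),
#'   `columns` (tibble: `name`, `condition`, `basis`, `task`, `empty`), `tr`,
#'   `n_scans`, and `frame_times`.
#' @export
build_design <- function(events, n_scans, tr = 2.73, hp_cutoff_s = 128,
                         microtime_bins = 16) {
  run_end <- n_scans * tr
  if (any(events$outcome_onset_s + events$outcome_duration_s > run_end)) {
    abort("events extend beyond the end of the run")
  }
  dt <- tr / microtime_bins
  n_fine <- n_scans * microtime_bins
  basis <- hrf_basis(dt)

  boxcar <- function(onsets, durations, amplitudes = 1) {
    u <- numeric(n_fine)
    amplitudes <- rep_len(amplitudes, length(onsets))
    for (j in seq_along(onsets)) {
      a <- floor(onsets[j] / dt) + 1
      b <- min(ceiling((onsets[j] + durations[j]) / dt), n_fine)
      if (a <= n_fine) u[a:b] <- u[a:b] + amplitudes[j]
    }
    u
  }

  convolve_sample <- function(u, h) {
    full <- convolve(u, rev(h), type = "open")[seq_len(n_fine)]
    full[(seq_len(n_scans) - 1) * microtime_bins + 1]
  }

  cue_types <- sort(unique(events$cue_type))
  conds <- list()
  for (ct in cue_types) {
    ev <- events[events$cue_type == ct & events$cue_included, ]
    conds[[paste0("cue_", ct)]] <-
      boxcar(ev$cue_onset_s, ev$cue_duration_s)
  }
  conds[["outcome"]] <- boxcar(events$outcome_onset_s, events$outcome_duration_s)
  mag <- events$magnitude_pence - mean(events$magnitude_pence)
  conds[["outcome_mag"]] <- boxcar(events$outcome_onset_s,
                                   events$outcome_duration_s, mag)

  bases <- c("hrf", "tderiv", "ddisp")
  cols <- list()
  info <- list()
  for (cn in names(conds)) {
    for (bi in seq_along(bases)) {
      h <- basis[[c("canonical", "temporal", "dispersion")[bi]]]
      nm <- paste0(cn, ":", bases[bi])
      cols[[nm]] <- convolve_sample(conds[[cn]], h)
      info[[nm]] <- tibble::tibble(
        name = nm, condition = cn, basis = bases[bi], task = TRUE,
        empty = all(conds[[cn]] == 0)
      )
    }
  }

  drifts <- cosine_drifts(n_scans, tr, hp_cutoff_s)
  for (j in seq_len(ncol(drifts))) {
    nm <- colnames(drifts)[j]
    cols[[nm]] <- drifts[, j]
    info[[nm]] <- tibble::tibble(name = nm, condition = "drift", basis = NA,
                                 task = FALSE, empty = FALSE)
  }
  cols[["intercept"]] <- rep(1, n_scans)
  info[["intercept"]] <- tibble::tibble(name = "intercept",
                                        condition = "intercept", basis = NA,
                                        task = FALSE, empty = FALSE)

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(
    list(X = X, columns = dplyr::bind_rows(info), tr = tr, n_scans = n_scans,
         frame_times = (seq_len(n_scans) - 1) * tr),
    class = "sat_design"
  )
}

#' @export
print.sat_design <- function(x, ...) {
  cat(sprintf("<SAT design> %d scans x %d columns (TR %.2f s)\n",
              x$n_scans, ncol(x$X), x$tr))
  invisible(x)
}

#' Residual-autocorrelation attenuation curve of a design
#'
#' OLS residuals are the projection `M = I - X(X'X)^-1 X'` of the noise, so
#' their lag-1 autocorrelation systematically understates the noise's true
#' AR(1) coefficient — markedly so when the design contains many smooth
#' regressors (drift terms, convolved boxcars) that absorb slowly varying
#' noise. This function computes, for a grid of generating coefficients
#' `rho`, the expected lag-1 autocorrelation of the projected residuals:
#' `tr(A M S M) / tr(M S M)` with `S` the AR(1) Toeplitz correlation matrix
#' and `A` the symmetrised lag operator. [fit_glm()] inverts this curve to
#' de-bias its pooled estimate; precompute it once when fitting many data
#' sets against the same design.
#'
#' @param X Design matrix (or `sat_design`).
#' @param grid Generating AR(1) coefficients at which to evaluate the curve.
#' @return A list with `grid` and `biased` (the expected residual
#'   autocorrelation at each grid value).
#' @export
ar1_calibration <- function(X, grid = seq(-0.9, 0.9, by = 0.15)) {
  if (inherits(X, "sat_design")) X <- X$X
  X <- X[, colSums(X != 0) > 0, drop = FALSE]
  n <- nrow(X)
  Q <- qr.Q(qr(X))
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  idx_up <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  idx_dn <- idx_up[, 2:1]
  biased <- vapply(grid, function(rho) {
    S <- rho^D
    B <- S - Q %*% crossprod(Q, S)          # M S
    B <- B - tcrossprod(B %*% Q, Q)         # M S M
    ((sum(B[idx_up]) + sum(B[idx_dn])) / 2) / sum(diag(B))
  }, numeric(1))
  list(grid = grid, biased = biased)
}

#' Fit a voxelwise GLM with AR(1) prewhitening
#'
#' Two-pass maximum-likelihood-style estimation: an ordinary least squares
#' fit, estimation of a single lag-1 autocorrelation coefficient pooled over
#' voxels from the OLS residuals — de-biased for the projection through the
#' design's [ar1_calibration()] curve — exact AR(1) whitening of both the
#' data and the design, and a refit on the whitened system. Empty task
#' columns (conditions with no events) are dropped before fitting and their
#' betas reported as `NA`.
#'
#' @param Y Numeric matrix, scans x voxels.
#' @param design A `sat_design` (or bare matrix).
#' @param grand_mean_scale If `TRUE`, scale the run so its grand mean signal
#'   is 100 (session-level global normalisation) before fitting.
#' @param ar_calibration Optional precomputed [ar1_calibration()] result for
#'   this design, to avoid recomputing it across repeated fits.
#' @return A `sat_glm` object with `betas` (columns x voxels, `NA` rows for
#'   dropped columns), `rho` (pooled AR(1) coefficient), `sigma2` (per-voxel
#'   residual variance, whitened domain), `cov_unscaled`
#'   (`(X'X)^-1` of the whitened design), `df_residual`, and the design.
#' @export
fit_glm <- function(Y, design, grand_mean_scale = FALSE,
                    ar_calibration = NULL) {
  X_full <- if (inherits(design, "sat_design")) design$X else design
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X_full)) abort("Y and the design have different numbers of scans")
  if (grand_mean_scale) {
    gm <- mean(Y)
    if (gm <= 0) abort("grand-mean scaling requires positive mean signal")
    Y <- Y * 100 / gm
  }

  keep <- colSums(X_full != 0) > 0
  X <- X_full[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; dependent columns: ",
                 paste(dep, collapse = ", ")))
  }

  ols_beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% ols_beta
  num <- sum(resid[-1, , drop = FALSE] * resid[-nrow(resid), , drop = FALSE])
  den <- sum(resid^2)
  if (den > sum(Y^2) * 1e-12 && den > 0) {
    raw <- num / den
    if (is.null(ar_calibration)) ar_calibration <- ar1_calibration(X)
    rho <- stats::approx(ar_calibration$biased, ar_calibration$grid,
                         xout = raw, rule = 2)$y
  } else {
    rho <- 0  # residuals at numerical noise level: treat as white
  }

  whiten <- function(M) {
    W <- M
    W[1, ] <- sqrt(1 - rho^2) * M[1, ]
    W[-1, ] <- M[-1, , drop = FALSE] - rho * M[-nrow(M), , drop = FALSE]
    W
  }
  Xw <- whiten(X)
  Yw <- whiten(Y)
  qrXw <- qr(Xw)
  beta <- qr.coef(qrXw, Yw)
  rw <- Yw - Xw %*% beta
  df <- nrow(Xw) - ncol(Xw)
  sigma2 <- colSums(rw^2) / df

  betas <- matrix(NA_real_, nrow = ncol(X_full), ncol = ncol(Y),
                  dimnames = list(colnames(X_full), colnames(Y)))
  betas[keep, ] <- beta

  structure(
    list(betas = betas, rho = rho, sigma2 = sigma2,
         cov_unscaled = chol2inv(chol(crossprod(Xw))),
         kept = keep, df_residual = df,
         design = if (inherits(design, "sat_design")) design else NULL),
    class = "sat_glm"
  )
}

#' @export
print.sat_glm <- function(x, ...) {
  cat(sprintf("<SAT first-level fit> %d columns x %d voxels, AR(1) rho = %.3f\n",
              nrow(x$betas), ncol(x$betas), x$rho))
  invisible(x)
}

#' Contrast weights over the canonical-HRF columns of a run design
#'
#' Three contrasts are defined. `"parametric_outcome"` puts unit weight on
#' the magnitude-modulation column. `"adaptive"` contrasts the two cue types
#' carrying the high-probability relevant feature against the two carrying
#' the low-probability feature (+1/2 and -1/2 per cue-type column).
#' `"aberrant"` contrasts the cue types containing the subjectively
#' high-rated irrelevant level against those containing the low-rated level,
#' using the block's relabelling; it therefore needs `relabel_high`.
#'
#' @param design A `sat_design`.
#' @param contrast `"parametric_outcome"`, `"adaptive"`, or `"aberrant"`.
#' @param version The [task_version()] the events came from (needed for
#'   `"adaptive"` and `"aberrant"`).
#' @param relabel_high For `"aberrant"`: the irrelevant-dimension level
#'   rated subjectively higher in this block.
#' @return A named weight vector over design columns.
#' @export
contrast_weights <- function(design, contrast, version = NULL,
                             relabel_high = NULL) {
  w <- stats::setNames(numeric(ncol(design$X)), colnames(design$X))
  hrf_cue <- design$columns$name[design$columns$basis == "hrf" &
                                 grepl("^cue_", design$columns$condition)]
  if (contrast == "parametric_outcome") {
    w["outcome_mag:hrf"] <- 1
    return(w)
  }
  if (is.null(version)) abort("`version` is required for cue contrasts")
  cue_feats <- strsplit(sub("^cue_", "", sub(":hrf$", "", hrf_cue)), "_")
  if (contrast == "adaptive") {
    has_high <- vapply(cue_feats, function(f) version$high_feature %in% f,
                       logical(1))
    w[hrf_cue] <- ifelse(has_high, 0.5, -0.5)
  } else if (contrast == "aberrant") {
    if (is.null(relabel_high)) abort("`relabel_high` is required for the aberrant contrast")
    has_high <- vapply(cue_feats, function(f) relabel_high %in% f, logical(1))
    w[hrf_cue] <- ifelse(has_high, 0.5, -0.5)
  } else {
    abort(paste0("unknown contrast: ", contrast))
  }
  w
}

#' Apply a contrast to a fitted run
#'
#' @param fit A `sat_glm` from [fit_glm()].
#' @param contrast Contrast name (see [contrast_weights()]) or a bare numeric
#'   weight vector over design columns.
#' @param version,relabel_high Passed to [contrast_weights()]. Supplying a
#'   tied relabelling (see [subjective_relabel()]) still works — the
#'   tie-broken level is used — but emits a warning when `relabel_tie` is
#'   `TRUE`.
#' @param relabel_tie Logical flag from [subjective_relabel()].
#' @return A list with `value` (per-voxel contrast estimate, weights dot
#'   betas), `se` (per-voxel standard error), `t` and `weights`.
#' @export
apply_contrast <- function(fit, contrast, version = NULL, relabel_high = NULL,
                           relabel_tie = FALSE) {
  if (!inherits(fit, "sat_glm")) abort("`fit` must be a sat_glm")
  if (is.numeric(contrast)) {
    w <- contrast
  } else {
    if (isTRUE(relabel_tie)) {
      warn("subjective relabelling was tied in this block; using the tie-broken mapping")
    }
    w <- contrast_weights(fit$design, contrast, version, relabel_high)
  }
  if (length(w) != nrow(fit$betas)) abort("contrast length does not match design columns")
  wk <- w[fit$kept]
  b <- fit$betas[fit$kept, , drop = FALSE]
  value <- as.numeric(crossprod(wk, b))
  var_c <- as.numeric(t(wk) %*% fit$cov_unscaled %*% wk)
  se <- sqrt(var_c * fit$sigma2)
  list(value = value, se = se, t = value / se, weights = w)
}

#' Fit the full first-level model for one subject
#'
#' Runs the complete within-subject pipeline: screens the log into events,
#' builds one design per block (each 64-trial block is one scanner run with
#' its own drift set and AR(1) estimate), fits each run, and computes the
#' three contrasts — parametric outcome modulation, adaptive reward
#' prediction, and aberrant reward prediction, the last using each block's
#' own subjective relabelling — averaging contrast estimates over the three
#' runs.
#'
#' @param log A `sat_subject` log.
#' @param bold A list of scans-x-voxels matrices, one per block.
#' @param n_scans Scans per run (all runs equal); default covers the block.
#' @param tr Repetition time (s).
#' @param grand_mean_scale Passed to [fit_glm()].
#' @return A `sat_first_level` object: `contrasts` (voxels x 3 matrix of
#'   run-averaged contrast values), `per_block` (list of per-run contrast
#'   results), `fits` (per-run `sat_glm`s), `relabel`.
#' @export
fit_first_level <- function(log, bold, n_scans = NULL, tr = 2.73,
                            grand_mean_scale = FALSE) {
  events <- screen_events(log)
  version <- log$schedule$version
  relabel <- subjective_relabel(log)
  blocks <- sort(unique(events$block))
  if (length(bold) != length(blocks)) abort("one BOLD matrix per block is required")

  per_block <- list()
  fits <- list()
  for (b in blocks) {
    ev <- events[events$block == b, ]
    ns <- n_scans %||% nrow(bold[[b]])
    design <- build_design(ev, n_scans = ns, tr = tr)
    fit <- fit_glm(bold[[b]], design, grand_mean_scale = grand_mean_scale)
    rl <- relabel[relabel$block == b, ]
    per_block[[b]] <- list(
      parametric_outcome = apply_contrast(fit, "parametric_outcome"),
      adaptive = apply_contrast(fit, "adaptive", version = version),
      aberrant = apply_contrast(fit, "aberrant", version = version,
                                relabel_high = rl$subjective_high,
                                relabel_tie = rl$tie)
    )
    fits[[b]] <- fit
  }

  cn <- c("parametric_outcome", "adaptive", "aberrant")
  contrasts <- sapply(cn, function(nm) {
    rowMeans(sapply(per_block, function(pb) pb[[nm]]$value))
  })
  structure(
    list(contrasts = contrasts, per_block = per_block, fits = fits,
         relabel = relabel, subject_id = log$subject_id),
    class = "sat_first_level"
  )
}

#' @export
print.sat_first_level <- function(x, ...) {
  cat(sprintf("<SAT first-level result, %s> %d voxels x %d contrasts over %d runs\n",
              x$subject_id, nrow(x$contrasts), ncol(x$contrasts),
              length(x$fits)))
  invisible(x)
}
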