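#' Build the 24-regressor motion nuisance set
#'
#' Expands six rigid-body motion parameters into the standard 24-column
#' nuisance block: the six parameters, their mean-centred squares, their
#' first-difference derivatives (zero at each run's first volume), and the
#' squared derivatives. Run intercepts and one linear drift per run are
#' returned as separate labelled blocks.
#'
#' @param motion Volumes x 6 matrix (runs concatenated row-wise), or a list
#'   of per-run matrices.
#' @param run_lengths Volumes per run; taken from the list when `motion` is
#'   a list.
#' @return A list of class `nuisance_set` with `motion24` (volumes x 24),
#'   `run_intercepts`, `run_drifts`, and `all` (everything column-bound with
#'   informative column names).
#' @export
build_nuisance <- function(motion, run_lengths = NULL) {
  if (is.list(motion) && !is.matrix(motion)) {
    run_lengths <- vapply(motion, nrow, integer(1))
    motion <- do.call(rbind, motion)
  }
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) abort("`motion` must have 6 columns.")
  if (is.null(run_lengths)) run_lengths <- nrow(motion)
  if (sum(run_lengths) != nrow(motion)) {
    abort("`run_lengths` must sum to the number of motion rows.")
  }
  bad <- which(!apply(motion, 2, function(z) all(is.finite(z))))
  if (length(bad)) {
    abort(sprintf("non-finite values in motion column(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  run_id <- rep(seq_along(run_lengths), run_lengths)
  center_by_run <- function(z) z - stats::ave(z, run_id)
  diff_by_run <- function(z) {
    d <- c(0, diff(z))
    d[c(1L, which(diff(run_id) != 0) + 1L)] <- 0
    d
  }
  sq <- apply(motion^2, 2, center_by_run)
  dv <- apply(motion, 2, diff_by_run)
  dsq <- dv^2
  motion24 <- cbind(motion, sq, dv, dsq)
  colnames(motion24) <- c(paste0("mot", 1:6), paste0("mot_sq", 1:6),
                          paste0("mot_d", 1:6), paste0("mot_dsq", 1:6))
  n_runs <- length(run_lengths)
  n <- nrow(motion)
  run_intercepts <- matrix(0, n, n_runs,
                           dimnames = list(NULL, paste0("run_int", seq_len(n_runs))))
  run_drifts <- matrix(0, n, n_runs,
                       dimnames = list(NULL, paste0("run_drift", seq_len(n_runs))))
  for (r in seq_len(n_runs)) {
    rows <- run_id == r
    run_intercepts[rows, r] <- 1
    run_drifts[rows, r] <- seq(-0.5, 0.5, length.out = run_lengths[r])
  }
  structure(list(motion24 = motion24, run_intercepts = run_intercepts,
                 run_drifts = run_drifts,
                 all = cbind(motion24, run_intercepts, run_drifts),
                 run_lengths = run_lengths),
            class = "nuisance_set")
}

#' Build a single-trial ("beta-series") GLM design
#'
#' One regressor per trial: a boxcar of `duration_s` seconds at the trial's
#' tasting onset, convolved with the canonical HRF on a 0.1-s internal grid
#' and resampled at the TR. Nuisance columns (24 motion regressors if
#' motion is supplied, run intercepts, per-run linear drifts) are carried
#' alongside, labelled, for VIF computation and joint estimation.
#'
#' @param trials Trial table (columns `run`, `onset_s`).
#' @param tr_s Repetition time in seconds.
#' @param run_lengths Volumes per run (named or in run order). When `NULL`,
#'   each run is sized to cover its last onset plus the HRF length.
#' @param duration_s Boxcar duration in seconds (3 by default; 8 reproduces
#'   the full-tasting-period variant).
#' @param hrf An [hrf_spec()].
#' @param motion Optional volumes x 6 motion matrix or per-run list; when
#'   given, the 24-column motion block enters the nuisance set.
#' @param dt Internal convolution grid step, seconds.
#' @return An object of class `single_trial_design`: list with `X` (volumes
#'   x regressors, trial columns first), `trial_cols`, `nuisance_cols`,
#'   `tr_s`, `run_lengths`, `trials`.
#' @export
build_single_trial_design <- function(trials, tr_s = 2.5, run_lengths = NULL,
                                      duration_s = 3, hrf = hrf_spec(),
                                      motion = NULL, dt = 0.1) {
  runs <- sort(unique(trials$run))
  if (is.null(run_lengths)) {
    run_lengths <- vapply(runs, function(r) {
      as.integer(ceiling((max(trials$onset_s[trials$run == r]) + hrf$length_s) / tr_s))
    }, integer(1))
  }
  if (length(run_lengths) != length(runs)) {
    abort("`run_lengths` must give one length per run.")
  }
  n_total <- sum(run_lengths)
  n_trials <- nrow(trials)
  X <- matrix(0, n_total, n_trials)
  offset <- c(0, cumsum(run_lengths))
  for (ri in seq_along(runs)) {
    sel <- which(trials$run == runs[ri])
    onsets <- trials$onset_s[sel]
    if (anyDuplicated(onsets)) {
      abort(sprintf("overlapping identical onsets in run %s.", runs[ri]))
    }
    if (any(onsets > run_lengths[ri] * tr_s)) {
      abort(sprintf("onset beyond the end of run %s.", runs[ri]))
    }
    cols <- convolve_events(onsets, rep(duration_s, length(sel)), 1,
                            run_lengths[ri], tr_s, hrf = hrf, dt = dt)
    X[(offset[ri] + 1):offset[ri + 1], sel] <- cols
  }
  colnames(X) <- paste0("trial", seq_len(n_trials))
  nuis <- if (is.null(motion)) {
    nr <- length(runs)
    n <- n_total
    run_id <- rep(seq_len(nr), run_lengths)
    ints <- matrix(0, n, nr, dimnames = list(NULL, paste0("run_int", 1:nr)))
    drfs <- matrix(0, n, nr, dimnames = list(NULL, paste0("run_drift", 1:nr)))
    for (r in seq_len(nr)) {
      ints[run_id == r, r] <- 1
      drfs[run_id == r, r] <- seq(-0.5, 0.5, length.out = run_lengths[r])
    }
    cbind(ints, drfs)
  } else {
    build_nuisance(motion, run_lengths)$all
  }
  structure(
    list(X = cbind(X, nuis),
         trial_cols = seq_len(n_trials),
         nuisance_cols = n_trials + seq_len(ncol(nuis)),
         tr_s = tr_s, run_lengths = run_lengths, trials = trials,
         duration_s = duration_s),
    class = "single_trial_design"
  )
}

#' Variance inflation factors of single-trial regressors
#'
#' For each trial regressor `k`, regresses the column on the full nuisance
#' block and returns `VIF_k = 1 / (1 - R_k^2)`, where `R_k^2` is the
#' coefficient of determination of that regression. Values are always
#' >= 1; a fit with `R^2` at 1 (within tolerance) yields `Inf`.
#'
#' @param design A [build_single_trial_design()] result.
#' @param trial_cols Which trial columns to evaluate (default: all).
#' @return Numeric vector of VIFs, one per requested trial column.
#' @export
compute_vif <- function(design, trial_cols = NULL) {
  stopifnot(inherits(design, "single_trial_design"))
  trial_cols <- trial_cols %||% design$trial_cols
  Z <- design$X[, design$nuisance_cols, drop = FALSE]
  if (ncol(Z) == 0) abort("nuisance block is empty.")
  qz <- qr(Z)
  vapply(trial_cols, function(k) {
    x <- design$X[, k]
    res <- qr.resid(qz, x)
    sst <- sum((x - mean(x))^2)
    if (sst < .Machine$double.eps) return(Inf)
    r2 <- 1 - sum(res^2) / sst
    if (r2 >= 1 - 1e-12) return(Inf)
    max(1, 1 / (1 - r2))
  }, numeric(1))
}

#' Estimate single-trial betas with VIF-based trial exclusion
#'
#' Fits the full GLM (trial regressors plus nuisance block) to every voxel
#' by ordinary least squares and returns the trial x voxel beta-series.
#' Trials whose VIF meets or exceeds `vif_threshold` are flagged excluded;
#' downstream mediation drops them listwise.
#'
#' @param bold Volumes x voxels matrix, a list of per-run matrices, or a
#'   `bold_sim` object.
#' @param design A [build_single_trial_design()] whose row count matches.
#' @param vif_threshold Exclusion threshold (default 2.5).
#' @return An object of class `beta_series`: list with `betas` (trial x
#'   voxel), `vif`, `included`, `excluded_count`, and `qc` (a tibble with
#'   one row per trial).
#' @export
estimate_betas <- function(bold, design, vif_threshold = 2.5) {
  stopifnot(inherits(design, "single_trial_design"))
  Y <- bold_matrix(bold)
  if (nrow(Y) != nrow(design$X)) {
    abort(sprintf("time dimension mismatch: %d volumes of data vs %d design rows.",
                  nrow(Y), nrow(design$X)))
  }
  qx <- qr(design$X)
  if (qx$rank < ncol(design$X)) {
    cn <- colnames(design$X)[qx$pivot[(qx$rank + 1):ncol(design$X)]]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s.",
                  paste(cn, collapse = ", ")))
  }
  vif <- compute_vif(design)
  included <- vif < vif_threshold
  if (!any(included)) {
    abort(sprintf("all %d trials excluded at VIF threshold %g; nothing to estimate.",
                  length(vif), vif_threshold))
  }
  coefs <- qr.coef(qx, Y)
  betas <- coefs[design$trial_cols, , drop = FALSE]
  rownames(betas) <- NULL
  structure(
    list(betas = betas, vif = vif, included = included,
         excluded_count = sum(!included),
         qc = tibble(trial = seq_along(vif), vif = vif, included = included)),
    class = "beta_series"
  )
}

# Accept a matrix, list of runs, or bold_sim, and return volumes x voxels.
bold_matrix <- function(bold) {
  if (inherits(bold, "bold_sim")) {
    return(do.call(rbind, lapply(bold$runs, `[[`, "data")))
  }
  if (is.list(bold) && !is.matrix(bold)) {
    parts <- lapply(bold, function(b) if (is.list(b)) b$data else b)
    return(do.call(rbind, parts))
  }
  as.matrix(bold)
}

#' Finite-impulse-response time-course estimation
#'
#' Model-free deconvolution of condition-wise peristimulus time courses:
#' one delta regressor per TR bin per condition, estimated jointly with an
#' intercept by OLS.
#'
#' @param bold Numeric vector (one voxel or an ROI average) for a single
#'   run, or volumes x 1 matrix.
#' @param onsets Numeric vector of event onsets (seconds), or a list of
#'   onset vectors, one per condition.
#' @param tr_s Repetition time in seconds (default 2.5, the bin width).
#' @param n_bins Number of peristimulus bins; `n_bins * tr_s` is the
#'   estimated window.
#' @return An object of class `fir_fit`: tibble with `condition`, `bin`,
#'   `time_s`, `estimate`, `se`; attribute `sigma` (residual s.d.).
#' @export
estimate_fir <- function(bold, onsets, tr_s = 2.5, n_bins = 10) {
  y <- as.numeric(bold)
  if (!is.list(onsets)) onsets <- list(cond1 = onsets)
  if (is.null(names(onsets))) names(onsets) <- paste0("cond", seq_along(onsets))
  n <- length(y)
  blocks <- lapply(onsets, function(on) {
    Xc <- matrix(0, n, n_bins)
    start <- round(on / tr_s) + 1L
    for (b in seq_len(n_bins)) {
      rows <- start + b - 1L
      rows <- rows[rows >= 1 & rows <= n]
      Xc[rows, b] <- Xc[rows, b] + 1
    }
    Xc
  })
  X <- cbind(1, do.call(cbind, blocks))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    abort("FIR design is rank deficient (overlapping windows or empty bins).")
  }
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / max(df, 1)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  out <- tibble(
    condition = rep(names(onsets), each = n_bins),
    bin = rep(seq_len(n_bins), length(onsets)),
    time_s = rep((seq_len(n_bins) - 1) * tr_s, length(onsets)),
    estimate = beta[-1],
    se = se[-1]
  )
  structure(out, sigma = sqrt(sigma2), df = df,
            class = c("fir_fit", class(out)))
}
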