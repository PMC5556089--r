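#' Simulation configuration for the planted-mediation generator
#'
#' Collects the population parameters of the two-level mediation model and
#' the BOLD noise model. Subject-level slopes `(a_i, b_i)` are drawn from a
#' bivariate normal with means `a_mean`, `b_mean`, standard deviations
#' `a_sd`, `b_sd` and covariance `ab_cov`, so the ground-truth group
#' indirect effect is `a_mean * b_mean + ab_cov`. The defaults
#' (`a_sd = 0.30`, `b_sd = 0.26`, `ab_cov = 0.05`) put the a-b correlation
#' at about 0.64, the size reported for value-region mediators in this
#' literature, and unit trial noise gives a moderate single-trial SNR.
#'
#' @param a_mean,a_sd Population mean / s.d. of the cue-to-mediator slope.
#' @param b_mean,b_sd Population mean / s.d. of the mediator-to-rating slope.
#' @param ab_cov Population covariance of `a_i` and `b_i`; must satisfy
#'   `|ab_cov| <= a_sd * b_sd`.
#' @param cprime_mean,cprime_sd Population mean / s.d. of the direct effect.
#' @param intercept_mean,intercept_sd Population mean / s.d. of the rating
#'   intercept (the 1-9 pleasantness scale centre sits near 5).
#' @param mediator_noise_sd Trial-level noise s.d. of the mediator (`e_m`).
#' @param rating_noise_sd Trial-level noise s.d. of the rating (`e_y`).
#' @param gamma_wine,gamma_payment Nuisance effects of wine identity and
#'   payment condition on the rating (covariates of no interest downstream).
#' @param moderator_lambda,moderator_noise_sd The per-subject moderator is
#'   generated as `w_i = moderator_lambda * a_i + N(0, moderator_noise_sd)`.
#' @param x_coding `"extremes"` codes the cheapest/most expensive price cues
#'   as -1/+1 with middle trials at 0 (and dropped from mediation);
#'   `"linear"` uses a centred linear code across all levels.
#' @param likert If `TRUE`, ratings are discretized to a 1-9 scale;
#'   continuous by default because clipping biases linear path recovery.
#' @param grid_dim 3-D voxel grid dimensions of the simulated volumes.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param n_mediator_voxels Number of voxels that carry the planted
#'   mediator signal; all others are null voxels.
#' @param mediator_voxels Optional fixed linear voxel indices for the
#'   planted mediators. Mediating regions are common across a group, so a
#'   multi-subject simulation should fix these once (e.g. via
#'   [simulate_study()] or the pipeline) rather than let every subject
#'   draw its own; `NULL` samples them from the seed.
#' @param drift_amplitude Amplitude of the per-voxel linear drift (signal
#'   units over a run).
#' @param ar_phi,ar_sd AR(1) coefficient (|phi| < 1) and innovation s.d. of
#'   the temporally autocorrelated voxel noise.
#' @param motion_leak Amplitude of motion-correlated nuisance signal leaked
#'   into every voxel.
#' @param hrf The [hrf_spec()] used to build BOLD responses.
#' @param seed Default seed stored with the configuration.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(a_mean = 0.5, a_sd = 0.30,
                       b_mean = 0.4, b_sd = 0.26,
                       ab_cov = 0.05,
                       cprime_mean = 0.1, cprime_sd = 0.05,
                       intercept_mean = 5, intercept_sd = 1,
                       mediator_noise_sd = 1, rating_noise_sd = 1,
                       gamma_wine = -0.1, gamma_payment = 0,
                       moderator_lambda = 1, moderator_noise_sd = 0.1,
                       x_coding = c("extremes", "linear"),
                       likert = FALSE,
                       grid_dim = c(10, 10, 10), voxel_size_mm = 2,
                       n_mediator_voxels = 5, mediator_voxels = NULL,
                       drift_amplitude = 1, ar_phi = 0.3, ar_sd = 1,
                       motion_leak = 0.5,
                       hrf = hrf_spec(), seed = NULL) {
  x_coding <- match.arg(x_coding)
  for (nm in c("a_sd", "b_sd", "cprime_sd", "intercept_sd",
               "mediator_noise_sd", "rating_noise_sd", "moderator_noise_sd",
               "drift_amplitude", "ar_sd", "motion_leak")) {
    stopifnot_scalar_number(get(nm), nm, lower = 0)
  }
  stopifnot_scalar_number(ar_phi, "ar_phi", lower = -1 + 1e-9, upper = 1 - 1e-9)
  if (abs(ab_cov) > a_sd * b_sd + 1e-12) {
    abort("`ab_cov` exceeds a_sd * b_sd: the (a, b) covariance matrix is not positive semidefinite.")
  }
  if (length(grid_dim) != 3 || any(grid_dim < 1)) {
    abort("`grid_dim` must be three positive integers.")
  }
  structure(
    list(a_mean = a_mean, a_sd = a_sd, b_mean = b_mean, b_sd = b_sd,
         ab_cov = ab_cov, cprime_mean = cprime_mean, cprime_sd = cprime_sd,
         intercept_mean = intercept_mean, intercept_sd = intercept_sd,
         mediator_noise_sd = mediator_noise_sd,
         rating_noise_sd = rating_noise_sd,
         gamma_wine = gamma_wine, gamma_payment = gamma_payment,
         moderator_lambda = moderator_lambda,
         moderator_noise_sd = moderator_noise_sd,
         x_coding = x_coding, likert = likert,
         grid_dim = as.integer(grid_dim), voxel_size_mm = voxel_size_mm,
         n_mediator_voxels = as.integer(n_mediator_voxels),
         mediator_voxels = mediator_voxels,
         drift_amplitude = drift_amplitude, ar_phi = ar_phi, ar_sd = ar_sd,
         motion_leak = motion_leak, hrf = hrf, seed = seed),
    class = "sim_config"
  )
}

#' Draw subject-level path coefficients
#'
#' Samples one row of mediation parameters per subject: `(a, b)` from the
#' configured bivariate normal, independent normal direct effects and
#' intercepts, and the moderator `w = lambda * a + noise`.
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed.
#' @return A tibble with columns `subject`, `a`, `b`, `cprime`,
#'   `intercept`, `moderator_w`.
#' @export
draw_subject_params <- function(config = sim_config(), n_subjects, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(n_subjects) || n_subjects < 2) {
    abort("`n_subjects` must be an integer >= 2.")
  }
  sigma <- matrix(c(config$a_sd^2, config$ab_cov,
                    config$ab_cov, config$b_sd^2), 2, 2)
  ei <- eigen(sigma, symmetric = TRUE)
  if (any(ei$values < -1e-12)) {
    abort("(a, b) covariance matrix is not positive semidefinite.")
  }
  fac <- ei$vectors %*% diag(sqrt(pmax(ei$values, 0))) %*% t(ei$vectors)
  with_seed_(seed, {
    z <- matrix(rnorm(2 * n_subjects), ncol = 2) %*% fac
    tibble(
      subject = seq_len(n_subjects),
      a = config$a_mean + z[, 1],
      b = config$b_mean + z[, 2],
      cprime = rnorm(n_subjects, config$cprime_mean, config$cprime_sd),
      intercept = rnorm(n_subjects, config$intercept_mean, config$intercept_sd),
      moderator_w = config$moderator_lambda * (config$a_mean + z[, 1]) +
        rnorm(n_subjects, 0, config$moderator_noise_sd)
    )
  })
}

#' Price-cue contrast codes
#'
#' @param price Integer price levels `1..n_levels` (1 = cheapest).
#' @param n_levels Number of price levels.
#' @param coding `"extremes"` (lowest = -1, highest = +1, middle 0) or
#'   `"linear"` (centred linear code).
#' @return Numeric contrast codes.
#' @export
price_contrast <- function(price, n_levels = 3, coding = c("extremes", "linear")) {
  coding <- match.arg(coding)
  if (coding == "extremes") {
    out <- rep(0, length(price))
    out[price == 1] <- -1
    out[price == n_levels] <- 1
    out
  } else {
    price - mean(seq_len(n_levels))
  }
}

#' Simulate trial-level mediator amplitudes and ratings
#'
#' Realizes the two-level mediation chain: per trial,
#' `m = a_i * x + e_m` and
#' `y = intercept_i + b_i * m + cprime_i * x + gamma_wine * wine_c +
#' gamma_payment * pay_c + e_y`, with `x` the price contrast code and
#' `wine_c`, `pay_c` centred nuisance codes.
#'
#' @param trials A trial table from [generate_design()] (one subject's
#'   design; it is reused for every row of `params`).
#' @param params Subject parameters from [draw_subject_params()]; one or
#'   more rows.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble: the trial table replicated per subject with added
#'   columns `subject`, `x` (contrast code), `m` (mediator amplitude) and
#'   filled `rating`.
#' @export
simulate_trial_data <- function(trials, params, config = sim_config(),
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_levels <- max(trials$price)
  x <- price_contrast(trials$price, n_levels, config$x_coding)
  wine_c <- trials$wine - mean(trials$wine)
  pay_c <- trials$payment - mean(trials$payment)
  nt <- nrow(trials)
  with_seed_(seed, {
    out <- purrr::map_dfr(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      m <- p$a * x + rnorm(nt, 0, config$mediator_noise_sd)
      y <- p$intercept + p$b * m + p$cprime * x +
        config$gamma_wine * wine_c + config$gamma_payment * pay_c +
        rnorm(nt, 0, config$rating_noise_sd)
      if (config$likert) y <- pmin(9, pmax(1, round(y)))
      dplyr::mutate(trials, subject = p$subject, x = x, m = m, rating = y,
                    .before = 1)
    })
    as_tibble(out)
  })
}

#' Simulate multi-run BOLD data with planted mediator voxels
#'
#' Builds one subject's 4-D BOLD data: in `n_mediator_voxels` randomly
#' placed voxels the per-trial mediator amplitude drives a
#' `tasting_duration_s`-second boxcar convolved with the canonical HRF; all
#' voxels additionally receive a linear drift, AR(1) noise and a
#' motion-correlated leak. Motion traces (6 rigid-body parameters per
#' volume, simulated as slow random walks) are returned for nuisance
#' regression.
#'
#' @param trials One subject's trial table (columns `run`, `onset_s`).
#' @param amplitudes Per-trial mediator amplitudes (e.g. the `m` column of
#'   [simulate_trial_data()]), in trial-table order.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param spec The [design_spec()] (supplies TR and tasting duration).
#' @return A list of class `bold_sim`: `runs` (per run, a list with `data`
#'   — volumes x voxels matrix —, `tr_s`, `run`, `n_vols`), `motion` (per
#'   run, volumes x 6 matrix), `mediator_voxels` (linear voxel indices
#'   carrying signal), and `grid` (a [volume_grid()]).
#' @export
simulate_bold <- function(trials, amplitudes, config = sim_config(),
                          seed = NULL, spec = design_spec()) {
  stopifnot(inherits(config, "sim_config"))
  if (length(amplitudes) != nrow(trials)) {
    abort("`amplitudes` must have one value per trial.")
  }
  n_vox <- prod(config$grid_dim)
  if (config$n_mediator_voxels > n_vox) {
    abort("grid too small for the requested number of mediator voxels.")
  }
  grid <- volume_grid(config$grid_dim, voxel_size_mm = config$voxel_size_mm)
  tr <- spec$tr_s
  with_seed_(seed, {
    mediator_voxels <- if (!is.null(config$mediator_voxels)) {
      mv <- as.integer(config$mediator_voxels)
      if (any(mv < 1 | mv > n_vox)) abort("`mediator_voxels` out of grid range.")
      sort(mv)
    } else {
      sort(sample.int(n_vox, config$n_mediator_voxels))
    }
    run_ids <- sort(unique(trials$run))
    runs <- vector("list", length(run_ids))
    motion <- vector("list", length(run_ids))
    for (ri in seq_along(run_ids)) {
      r <- run_ids[ri]
      sel <- trials$run == r
      onsets <- trials$onset_s[sel]
      amps <- amplitudes[sel]
      n_vols <- as.integer(ceiling((max(onsets) + config$hrf$length_s) / tr))
      signal <- convolve_events(onsets, rep(spec$tasting_duration_s, sum(sel)),
                                amps, n_vols, tr, hrf = config$hrf,
                                separate = FALSE)
      mot <- matrix(0, n_vols, 6)
      for (j in 1:6) mot[, j] <- cumsum(rnorm(n_vols, 0, 0.02))
      colnames(mot) <- c("x", "y", "z", "roll", "pitch", "yaw")
      dat <- matrix(0, n_vols, n_vox)
      if (config$ar_sd > 0) {
        innov <- matrix(rnorm(n_vols * n_vox, 0, config$ar_sd), n_vols, n_vox)
        if (abs(config$ar_phi) > 0) {
          dat <- apply(innov, 2, function(e)
            as.numeric(stats::filter(e, config$ar_phi, method = "recursive")))
        } else dat <- innov
      }
      if (config$drift_amplitude > 0) {
        ramp <- seq(-0.5, 0.5, length.out = n_vols)
        slopes <- runif(n_vox, -1, 1) * config$drift_amplitude
        dat <- dat + outer(ramp, slopes)
      }
      if (config$motion_leak > 0) {
        leak_w <- matrix(rnorm(6 * n_vox), 6, n_vox)
        dat <- dat + config$motion_leak * (mot %*% leak_w)
      }
      dat[, mediator_voxels] <- dat[, mediator_voxels] + signal
      runs[[ri]] <- list(data = dat, tr_s = tr, run = r, n_vols = n_vols)
      motion[[ri]] <- mot
    }
    structure(list(runs = runs, motion = motion,
                   mediator_voxels = mediator_voxels, grid = grid),
              class = "bold_sim")
  })
}

#' Simulate a complete multi-subject study (behavioral level)
#'
#' Convenience wrapper: draws subject parameters, one pseudo-randomized
#' design per subject, and trial-level mediators and ratings.
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of subjects.
#' @param spec A [design_spec()].
#' @param seed Integer seed controlling every stage.
#' @return A list with `trials` (long tibble over subjects, with `x`, `m`,
#'   `rating`), `params` (subject parameter tibble), `spec` and `config`.
#' @export
simulate_study <- function(config = sim_config(), n_subjects = 30,
                           spec = design_spec(), seed = NULL) {
  with_seed_(seed, {
    params <- draw_subject_params(config, n_subjects)
    trials <- purrr::map_dfr(seq_len(n_subjects), function(i) {
      d <- generate_design(spec)
      simulate_trial_data(d, params[i, ], config)
    })
    list(trials = trials, params = params, spec = spec, config = config)
  })
}
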