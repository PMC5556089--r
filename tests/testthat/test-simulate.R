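test_that("subject parameter moments converge to the configured values", {
  cfg <- sim_config(a_mean = 0.5, b_mean = 0.4, ab_cov = 0)
  p <- draw_subject_params(cfg, 10000, seed = 1)
  se_a <- cfg$a_sd / sqrt(10000)
  se_b <- cfg$b_sd / sqrt(10000)
  expect_lt(abs(mean(p$a) - 0.5), 3 * se_a)
  expect_lt(abs(mean(p$b) - 0.4), 3 * se_b)
  # zero-covariance case: sample cov within 3 Monte-Carlo s.e. of 0
  se_cov <- cfg$a_sd * cfg$b_sd / sqrt(10000)
  expect_lt(abs(stats::cov(p$a, p$b)), 3 * se_cov)

  cfg2 <- sim_config(ab_cov = 0.05)
  p2 <- draw_subject_params(cfg2, 10000, seed = 2)
  expect_lt(abs(stats::cov(p2$a, p2$b) - 0.05), 4 * se_cov)
})

test_that("parameter draws are reproducible and reject invalid covariances", {
  cfg <- sim_config()
  expect_identical(draw_subject_params(cfg, 20, seed = 5),
                   draw_subject_params(cfg, 20, seed = 5))
  expect_error(sim_config(ab_cov = 1), "positive semidefinite")
  expect_error(draw_subject_params(cfg, 1), ">= 2")
})

test_that("noise-free trial simulation realizes the exact mediation chain", {
  cfg <- noise_free_config(a_mean = 1, a_sd = 0, b_mean = 1, b_sd = 0,
                           ab_cov = 0, cprime_mean = 0, cprime_sd = 0,
                           gamma_wine = 0, intercept_sd = 0)
  d <- generate_design(small_spec(), seed = 1)
  p <- draw_subject_params(cfg, 2, seed = 1)
  td <- simulate_trial_data(d, p[1, ], cfg, seed = 1)
  # m = x and y = x + intercept exactly
  expect_equal(td$m, td$x)
  expect_equal(td$rating, td$x + p$intercept[1])
})

test_that("null path a gives a mediator uncorrelated with the cue", {
  cfg <- sim_config(a_mean = 0, a_sd = 0, ab_cov = 0)
  d <- generate_design(seed = 2)
  td <- simulate_trial_data(d, draw_subject_params(cfg, 2, seed = 1)[1, ],
                            cfg, seed = 3)
  expect_lt(abs(stats::cov(td$m, td$x)), 3 / sqrt(nrow(td)))
})

test_that("OLS refit at vanishing noise returns the planted coefficients", {
  d <- generate_design(seed = 3)
  # noise-free mediator equation: path a recovered to machine precision
  # (the joint y equation is then unidentified -- m is proportional to x)
  cfg_a <- sim_config(mediator_noise_sd = 0, rating_noise_sd = 1)
  p <- draw_subject_params(cfg_a, 3, seed = 4)
  td_a <- simulate_trial_data(d, p, cfg_a, seed = 5)
  paths_a <- fit_subject_paths(td_a)
  expect_equal(paths_a$a, p$a, tolerance = 1e-12)
  # noise-free rating equation: b and c' recovered to machine precision
  cfg_y <- sim_config(mediator_noise_sd = 0.5, rating_noise_sd = 0)
  td_y <- simulate_trial_data(d, p, cfg_y, seed = 6)
  paths_y <- fit_subject_paths(td_y)
  expect_equal(paths_y$b, p$b, tolerance = 1e-10)
  expect_equal(paths_y$cprime, p$cprime, tolerance = 1e-10)
})

test_that("noise-free BOLD equals the HRF-convolved boxcar in signal voxels", {
  spec <- small_spec()
  cfg <- noise_free_config()
  d <- generate_design(spec, seed = 1)
  amps <- rep(0, nrow(d)); amps[5] <- 1   # single active trial
  b <- simulate_bold(d, amps, cfg, seed = 1, spec = spec)
  run1 <- d$run[5]
  sig <- b$runs[[run1]]$data[, b$mediator_voxels[1]]
  ref <- as.numeric(brainmediate:::convolve_events(
    d$onset_s[5], spec$tasting_duration_s, 1, b$runs[[run1]]$n_vols,
    spec$tr_s, hrf = cfg$hrf))
  expect_equal(sig, ref, tolerance = 1e-12)
  # amplitude sets the fine-grid peak at 1; TR sampling can fall slightly off
  expect_gt(max(sig), 0.9)
  expect_lte(max(sig), 1 + 1e-9)
  null_vox <- setdiff(seq_len(prod(cfg$grid_dim)), b$mediator_voxels)
  expect_true(all(b$runs[[run1]]$data[, null_vox] == 0))
})

test_that("pure AR(1) noise has the closed-form stationary variance", {
  spec <- design_spec(reps_per_condition = 9, n_runs = 1)  # long run
  phi <- 0.5
  cfg <- sim_config(drift_amplitude = 0, motion_leak = 0, ar_phi = phi,
                    ar_sd = 1, grid_dim = c(4, 4, 4), n_mediator_voxels = 1)
  d <- generate_design(spec, seed = 2)
  b <- simulate_bold(d, rep(0, nrow(d)), cfg, seed = 3, spec = spec)
  v <- apply(b$runs[[1]]$data, 2, stats::var)
  expect_equal(mean(v), 1 / (1 - phi^2), tolerance = 0.05)
})

test_that("BOLD simulation is reproducible and validates its grid", {
  spec <- small_spec()
  cfg <- noise_free_config()
  d <- generate_design(spec, seed = 1)
  b1 <- simulate_bold(d, rep(1, nrow(d)), cfg, seed = 9, spec = spec)
  b2 <- simulate_bold(d, rep(1, nrow(d)), cfg, seed = 9, spec = spec)
  expect_identical(b1$runs[[1]]$data, b2$runs[[1]]$data)
  cfg_big <- sim_config(grid_dim = c(2, 2, 2), n_mediator_voxels = 100)
  expect_error(simulate_bold(d, rep(1, nrow(d)), cfg_big, seed = 1,
                             spec = spec),
               "grid too small")
})
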