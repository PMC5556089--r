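test_that("motion nuisance expansion yields exactly 24 labelled columns", {
  set.seed(1)
  motion <- list(matrix(rnorm(40 * 6, sd = 0.1), 40, 6),
                 matrix(rnorm(30 * 6, sd = 0.1), 30, 6))
  nu <- build_nuisance(motion)
  expect_equal(ncol(nu$motion24), 24)
  expect_equal(ncol(nu$run_intercepts), 2)
  expect_equal(ncol(nu$run_drifts), 2)
  expect_equal(ncol(nu$all), 28)
  # squares are mean-centred within run
  sq <- nu$motion24[, 7:12]
  run_id <- rep(1:2, c(40, 30))
  expect_true(all(abs(tapply(sq[, 1], run_id, mean)) < 1e-12))
})

test_that("constant and ramp motion traces expand as calculus dictates", {
  motion <- matrix(5, 20, 6)
  nu <- build_nuisance(motion, run_lengths = 20)
  expect_true(all(nu$motion24[, 7:24] == 0))   # centred squares, derivs, sq-derivs
  expect_equal(qr(nu$all)$rank, 2)             # intercept + drift only

  ramp <- matrix(seq_len(20), 20, 6)
  nu2 <- build_nuisance(ramp, run_lengths = 20)
  d1 <- nu2$motion24[, 13]
  expect_true(all(d1[-1] == 1))                # constant derivative within run
  expect_equal(d1[1], 0)                       # zero-padded at run start

  bad <- motion; bad[3, 2] <- NA
  expect_error(build_nuisance(bad, run_lengths = 20), "column")
})

test_that("VIF matches its definition and the printed exclusion threshold", {
  # construct a design with R^2 exactly 0.6 against the nuisance block
  n <- 50
  set.seed(42)
  z <- scale(rnorm(n))[, 1]; z <- z / sqrt(sum(z^2))
  e <- stats::resid(lm(rnorm(n) ~ z)); e <- scale(e)[, 1] / sqrt(sum(scale(e)[, 1]^2))
  x <- sqrt(0.6) * z + sqrt(0.4) * e
  des <- structure(list(X = cbind(trial1 = x, int = rep(1, n), z = z),
                        trial_cols = 1L, nuisance_cols = 2:3, tr_s = 2.5),
                   class = "single_trial_design")
  expect_equal(compute_vif(des), 2.5, tolerance = 1e-8)

  # orthogonal trial column (centred, orthogonal to z) has VIF 1
  des_orth <- des; des_orth$X[, 1] <- e
  expect_equal(compute_vif(des_orth), 1, tolerance = 1e-8)

  # adding a nuisance column orthogonal to everything leaves VIF unchanged
  o <- stats::resid(lm(rnorm(n) ~ x + z)); o <- o / sqrt(sum(o^2))
  des_plus <- structure(list(X = cbind(des$X, o = o), trial_cols = 1L,
                             nuisance_cols = 2:4, tr_s = 2.5),
                        class = "single_trial_design")
  expect_equal(compute_vif(des_plus), compute_vif(des), tolerance = 1e-10)
})

test_that("regression VIF equals the correlation-matrix-inversion oracle", {
  set.seed(7)
  for (i in 1:25) {
    X <- matrix(rnorm(20 * 5), 20, 5)
    des <- structure(list(X = cbind(trial1 = X[, 1], int = rep(1, 20),
                                    X[, 2:5]),
                          trial_cols = 1L, nuisance_cols = 2:6, tr_s = 2.5),
                     class = "single_trial_design")
    oracle <- solve(stats::cor(X))[1, 1]
    expect_equal(compute_vif(des), oracle, tolerance = 1e-8)
  }
})

test_that("single-trial GLM recovers planted amplitudes exactly without noise", {
  spec <- small_spec()
  cfg <- noise_free_config()
  d <- generate_design(spec, seed = 2)
  p <- draw_subject_params(cfg, 2, seed = 3)
  td <- simulate_trial_data(d, p[1, ], cfg, seed = 4)
  b <- simulate_bold(td, td$m, cfg, seed = 5, spec = spec)
  des <- build_single_trial_design(
    td, tr_s = spec$tr_s,
    run_lengths = vapply(b$runs, function(r) r$n_vols, integer(1)),
    motion = b$motion)
  bs <- estimate_betas(b, des)
  for (v in b$mediator_voxels) {
    expect_equal(unname(bs$betas[, v]), td$m, tolerance = 1e-8)
  }
  null_vox <- setdiff(seq_len(prod(cfg$grid_dim)), b$mediator_voxels)
  expect_true(all(abs(bs$betas[, null_vox]) < 1e-10))  # all-zero voxels
  expect_equal(bs$excluded_count, 0)
  expect_true(all(bs$vif >= 1))
})

test_that("beta estimates are invariant to adding nuisance-span signal", {
  spec <- small_spec()
  cfg <- noise_free_config()
  d <- generate_design(spec, seed = 6)
  td <- simulate_trial_data(d, draw_subject_params(cfg, 2, seed = 1)[1, ],
                            cfg, seed = 2)
  b <- simulate_bold(td, td$m, cfg, seed = 3, spec = spec)
  des <- build_single_trial_design(
    td, tr_s = spec$tr_s,
    run_lengths = vapply(b$runs, function(r) r$n_vols, integer(1)),
    motion = b$motion)
  Y <- do.call(rbind, lapply(b$runs, `[[`, "data"))
  bs0 <- estimate_betas(Y, des)
  shift <- des$X[, des$nuisance_cols] %*% rnorm(length(des$nuisance_cols))
  bs1 <- estimate_betas(Y + matrix(shift, nrow(Y), ncol(Y)), des)
  expect_equal(bs0$betas, bs1$betas, tolerance = 1e-7)
})

test_that("degenerate VIF thresholds and excluded trials are handled", {
  spec <- small_spec()
  cfg <- noise_free_config()
  d <- generate_design(spec, seed = 8)
  td <- simulate_trial_data(d, draw_subject_params(cfg, 2, seed = 1)[1, ],
                            cfg, seed = 2)
  b <- simulate_bold(td, td$m, cfg, seed = 3, spec = spec)
  des <- build_single_trial_design(
    td, tr_s = spec$tr_s,
    run_lengths = vapply(b$runs, function(r) r$n_vols, integer(1)),
    motion = b$motion)
  expect_error(estimate_betas(b, des, vif_threshold = 1), "excluded")
  expect_error(estimate_betas(matrix(0, 10, 3), des), "mismatch")
})

test_that("trial exclusion stays rare at realistic noise levels", {
  spec <- design_spec()
  cfg <- sim_config()
  d <- generate_design(spec, seed = 11)
  td <- simulate_trial_data(d, draw_subject_params(cfg, 2, seed = 1)[1, ],
                            cfg, seed = 2)
  b <- simulate_bold(td, td$m, cfg, seed = 3, spec = spec)
  des <- build_single_trial_design(
    td, tr_s = spec$tr_s,
    run_lengths = vapply(b$runs, function(r) r$n_vols, integer(1)),
    motion = b$motion)
  vif <- compute_vif(des)
  expect_lt(mean(vif >= 2.5), 0.05)
})

test_that("FIR deconvolution is unbiased for null conditions and fails on rank deficiency", {
  withr::with_seed(5, {
    tr <- 2.5
    on_active <- seq(0, by = 50, length.out = 12)
    on_null <- seq(25, by = 50, length.out = 12)
    trials <- tibble::tibble(run = 1L, onset_s = sort(c(on_active, on_null)))
    amps <- ifelse(trials$onset_s %in% on_active, 1, 0)
    cfg <- sim_config(grid_dim = c(2, 2, 2), n_mediator_voxels = 1,
                      drift_amplitude = 0, motion_leak = 0, ar_phi = 0,
                      ar_sd = 0.05)
    b <- simulate_bold(trials, amps, cfg, seed = 6, spec = design_spec())
    y <- b$runs[[1]]$data[, b$mediator_voxels[1]]
    fir <- estimate_fir(y, list(active = on_active, null = on_null),
                        tr_s = tr, n_bins = 10)
    nul <- fir[fir$condition == "null", ]
    expect_true(all(abs(nul$estimate) <= 4 * nul$se))
    # overlapping identical windows make the design unidentifiable
    expect_error(estimate_fir(y, list(a = on_active, b = on_active),
                              tr_s = tr, n_bins = 10),
                 "rank deficient")
  })
})
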