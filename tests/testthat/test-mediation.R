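test_that("a perfect noise-free chain yields textbook path coefficients", {
  d <- tibble::tibble(subject = 1L,
                      x = rep(c(-1, 1), 10),
                      wine = rep(1:2, 10), payment = rep(0:1, each = 10))
  d$m <- d$x
  d$rating <- d$m
  p <- fit_subject_paths(d)
  expect_equal(p$a, 1, tolerance = 1e-12)
  expect_equal(p$b, 1, tolerance = 1e-12)
  expect_equal(p$c, 1, tolerance = 1e-12)
  expect_equal(p$cprime, 0, tolerance = 1e-12)
})

test_that("c = c' + a*b holds exactly with shared covariates", {
  withr::with_seed(11, {
    for (i in 1:50) {
      d <- random_trial_data(30 + i)
      p <- fit_subject_paths(d, drop_middle = FALSE)
      expect_lt(abs(p$c - p$cprime - p$ab), 1e-10)
    }
  })
})

test_that("a null mediator produces near-zero a and ab paths", {
  withr::with_seed(2, {
    d <- random_trial_data(5000)
    p <- fit_subject_paths(d, drop_middle = FALSE)
    expect_lt(abs(p$a), 0.05)
    expect_lt(abs(p$ab), 0.05)
  })
})

test_that("degenerate and underpowered inputs are rejected or flagged", {
  d <- random_trial_data(5)
  expect_error(fit_subject_paths(d, drop_middle = FALSE), "complete trials")
  d2 <- random_trial_data(30); d2$x <- 1
  expect_error(fit_subject_paths(d2, drop_middle = FALSE), "constant")
  d3 <- random_trial_data(30); d3$m <- 2
  p <- fit_subject_paths(d3, drop_middle = FALSE)
  expect_true(p$degenerate)
  expect_true(is.na(p$b))
})

test_that("the group decomposition matches hand computation", {
  paths <- tibble::tibble(subject = 1:3, a = c(1, 2, 3), b = c(1, 2, 3),
                          c = 0, cprime = 0, ab = c(1, 4, 9))
  g <- group_decompose(paths)
  expect_equal(g$mean_ab, 14 / 3)
  expect_equal(g$prod_means, 4)
  expect_equal(g$cov_ab, 2 / 3)
  # constant b collapses the covariance term
  paths2 <- tibble::tibble(subject = 1:4, a = rnorm(4), b = 2)
  g2 <- group_decompose(paths2)
  expect_equal(g2$cov_ab, 0, tolerance = 1e-14)
  expect_equal(g2$mean_ab, mean(paths2$a) * 2)
})

test_that("the indirect-effect identity holds on random path matrices", {
  withr::with_seed(3, {
    for (i in 1:200) {
      pm <- random_path_matrix(sample(2:40, 1))
      g <- group_decompose(pm)
      expect_lt(abs(g$mean_ab - g$prod_means - g$cov_ab), 1e-12)
    }
  })
})

test_that("bootstrap p-values respect the floor, ties and determinism", {
  pm <- random_path_matrix(20, seed = 4)
  pm$a <- pm$a + 10; pm$b <- pm$b + 10; pm$ab <- pm$a * pm$b  # overwhelming effect
  b1 <- bootstrap_inference(pm, n_boot = 500, seed = 1)
  expect_equal(b1$p[b1$path == "ab"], 2 / 500)
  b2 <- bootstrap_inference(pm, n_boot = 500, seed = 1)
  expect_identical(b1, b2)
  # all-identical rows give a zero-width degenerate interval at the floor
  pm3 <- tibble::tibble(subject = 1:6, a = 1, b = 1, c = 1, cprime = 0, ab = 1)
  b3 <- bootstrap_inference(pm3, n_boot = 200, seed = 2)
  expect_true(all(b3$degenerate[b3$path %in% c("a", "b", "ab")]))
  expect_equal(b3$p[b3$path == "ab"], 2 / 200)
  expect_error(bootstrap_inference(random_path_matrix(3, seed = 1)),
               "at least 5")
})

test_that("bootstrap CIs contain the point estimate", {
  pm <- random_path_matrix(25, seed = 6)
  b <- bootstrap_inference(pm, n_boot = 2000, seed = 7)
  expect_true(all(b$ci_lower <= b$estimate & b$estimate <= b$ci_upper))
  expect_true(all(b$p > 0 & b$p <= 1))
})

test_that("bootstrap p for the indirect effect is uniform under a permuted-cue null", {
  # Kolmogorov-Smirnov check across replicates: permuting x within subject
  # destroys the a path, so the two-tailed bootstrap p of mean(ab) should be
  # (approximately) uniform on (0, 1].
  cfg <- sim_config()
  n_sub <- 30
  base <- simulate_study(cfg, n_subjects = n_sub, seed = 21)
  ps <- withr::with_seed(22, {
    vapply(seq_len(1000), function(r) {
      d <- base$trials
      d$x <- unlist(lapply(split(d$x, d$subject), sample), use.names = FALSE)
      paths <- fit_subject_paths(d)
      b <- bootstrap_inference(paths, n_boot = 500)
      b$p[b$path == "ab"]
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mediation classification distinguishes full, partial and none", {
  mk <- function(p_ab, p_cp) {
    tibble::tibble(path = c("ab", "cprime"), p = c(p_ab, p_cp))
  }
  expect_equal(classify_mediation(mk(0.001, 0.001)), "partial")
  expect_equal(classify_mediation(mk(0.001, 0.4)), "full")
  expect_equal(classify_mediation(mk(0.2, 0.001)), "none")
})

test_that("voxelwise mediation reduces to the scalar pipeline on one voxel", {
  cfg <- sim_config()
  st <- simulate_study(cfg, n_subjects = 8, seed = 31)
  subjects <- lapply(split(st$trials, st$trials$subject), function(d) {
    list(x = d$x, m = matrix(d$m, ncol = 1), y = d$rating,
         covariates = cbind(d$wine, d$payment))
  })
  maps <- voxelwise_mediation(subjects, n_boot = 300, seed = 5)
  paths <- fit_subject_paths(st$trials)
  boot <- bootstrap_inference(paths, n_boot = 300, seed = 5)
  for (pth in c("a", "b", "ab", "cprime", "c")) {
    expect_equal(maps$estimate[maps$path == pth],
                 boot$estimate[boot$path == pth], tolerance = 1e-10)
    expect_equal(maps$p[maps$path == pth], boot$p[boot$path == pth])
  }
})

test_that("planted mediator voxels dominate a null background", {
  cfg <- sim_config()
  st <- simulate_study(cfg, n_subjects = 15, seed = 41)
  n_vox <- 60; planted <- c(7, 23, 44)
  subjects <- withr::with_seed(42, {
    lapply(split(st$trials, st$trials$subject), function(d) {
      M <- matrix(rnorm(nrow(d) * n_vox), nrow(d), n_vox)
      M[, planted] <- M[, planted] + d$m
      list(x = d$x, m = M, y = d$rating,
           covariates = cbind(d$wine, d$payment))
    })
  })
  maps <- voxelwise_mediation(subjects, n_boot = 500, seed = 43)
  ab <- maps[maps$path == "ab", ]
  top <- ab$voxel[order(ab$p, -abs(ab$estimate))][seq_along(planted)]
  expect_setequal(top, planted)
})
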