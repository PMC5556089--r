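test_that("within-subject z-scoring uses the sample-s.d. convention", {
  expect_equal(zscore_within_subject(c(1, 2, 3), rep(1, 3)), c(-1, 0, 1))
  # idempotence: already standardized input is unchanged
  z <- zscore_within_subject(rnorm(20), rep(1, 20))
  expect_equal(zscore_within_subject(z, rep(1, 20)), z, tolerance = 1e-12)
  # groupwise oracle: two subjects on different scales, each standardized
  # independently
  v <- c(1, 2, 3, 100, 200, 300)
  s <- c(1, 1, 1, 2, 2, 2)
  expect_equal(zscore_within_subject(v, s),
               c(scale(c(1, 2, 3))[, 1], scale(c(100, 200, 300))[, 1]))
  expect_error(zscore_within_subject(c(1, 1, 1), rep(1, 3)), "constant")
})

make_lmm_data <- function(n_subjects = 12, seed = 31, intercept_sd = 1,
                          config = NULL) {
  cfg <- config %||% sim_config(intercept_sd = intercept_sd)
  simulate_study(cfg, n_subjects = n_subjects, seed = seed)$trials
}

test_that("the rating mixed model has the printed shape: 12 terms, df = n - 12", {
  d <- make_lmm_data()
  fit <- fit_rating_lmm(d)
  expect_equal(fit$n_fixed, 12)
  expect_equal(fit$df, fit$n_obs - 12)
  expect_equal(fit$n_obs, nrow(d))
  expect_setequal(
    fit$fixed$term,
    c("Intercept", "Trial number", "Wine", "Price cue", "Payment",
      "Trial number by Wine", "Trial number by Price cue",
      "Trial number by Payment", "Wine by Price cue", "Wine by Payment",
      "Price cue by Payment", "Trial number by Price cue by Payment"))
  g <- glance(fit)
  expect_equal(g$deviance, -2 * g$logLik)
})

test_that("with no subject heterogeneity the LMM collapses to pooled OLS", {
  d <- make_lmm_data(intercept_sd = 0, seed = 7)
  fit <- fit_rating_lmm(d)
  # refit the same standardized design by plain OLS
  ols <- stats::lm(stats::formula(fit$model, fixed.only = TRUE),
                   data = fit$model@frame)
  expect_equal(unname(fit$fixed$estimate), unname(stats::coef(ols)),
               tolerance = 0.02)
  expect_lt(fit$ranef_sd, 0.1)
})

test_that("the LMM recovers a planted linear price-cue effect", {
  cfg <- sim_config()
  d <- make_lmm_data(n_subjects = 30, seed = 13, config = cfg)
  fit <- fit_rating_lmm(d)
  # per-subject slope on the extremes contrast is a*b + c'; z-scoring price
  # rescales it by the within-subject s.d. of the price code
  slope_x <- cfg$a_mean * cfg$b_mean + cfg$ab_cov + cfg$cprime_mean
  sd_price <- stats::sd(rep(1:3, each = 36))
  expected <- slope_x * sd_price
  row <- fit$fixed[fit$fixed$term == "Price cue", ]
  expect_lt(abs(row$estimate - expected), 3 * row$se)
  expect_lt(row$p, 0.001)
  pay <- fit$fixed[fit$fixed$term == "Payment", ]
  expect_gt(pay$p, 0.001)  # payment was simulated null
})

test_that("duplicating every observation tightens but does not move estimates", {
  d <- make_lmm_data(n_subjects = 8, seed = 17)
  fit1 <- fit_rating_lmm(d)
  d2 <- dplyr::bind_rows(d, d)
  fit2 <- fit_rating_lmm(d2)
  expect_equal(fit1$fixed$estimate, fit2$fixed$estimate, tolerance = 0.02)
  # within-subject terms gain precision; the intercept's SE is dominated by
  # the between-subject variance, which duplication cannot reduce
  not_int <- fit1$fixed$term != "Intercept"
  expect_true(all(fit2$fixed$se[not_int] < fit1$fixed$se[not_int]))
})

test_that("paired contrast equals the one-sample t on differences", {
  withr::with_seed(23, {
    for (i in 1:10) {
      a <- rnorm(12); b <- rnorm(12)
      res <- paired_contrast(a, b)
      d <- a - b
      t_oracle <- mean(d) / (stats::sd(d) / sqrt(length(d)))
      expect_equal(res$t, t_oracle, tolerance = 1e-12)
      expect_equal(res$df, 11)
      expect_equal(res$p, 2 * stats::pt(-abs(t_oracle), 11), tolerance = 1e-12)
    }
  })
  ident <- paired_contrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_true(ident$degenerate)
  shifted <- paired_contrast(c(1, 2, 3, 4) + 1, c(1, 2, 3, 4))
  expect_true(is.infinite(shifted$t))
  expect_equal(shifted$df, 3)
})
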