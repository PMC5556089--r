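#' Fit the three path regressions for each subject
#'
#' Per subject, estimates by OLS the total effect `c` (`y ~ x + covariates`),
#' the cue-to-mediator path `a` (`m ~ x + covariates`), and jointly the
#' mediator-to-outcome path `b` and direct effect `c'`
#' (`y ~ m + x + covariates`). The indirect effect is `ab = a * b`. With
#' identical covariates across the three equations the OLS decomposition
#' `c = c' + a * b` holds exactly for every subject.
#'
#' @param data Trial-level tibble. With a `subject` column, one row of path
#'   coefficients is returned per subject.
#' @param x,m,y Names of the cue, mediator and outcome columns (defaults
#'   `"x"`, `"m"`, `"rating"`).
#' @param covariates Character vector naming trial-level covariates of no
#'   interest (e.g. `c("wine", "payment")`), entered (centred) in all three
#'   equations.
#' @param drop_middle For the extremes contrast: drop trials with `x == 0`
#'   (the middle price level) before fitting. Default `TRUE`.
#' @param min_trials Minimum complete trials required per subject.
#' @return A `path_matrix` tibble: one row per subject with columns
#'   `subject`, `a`, `b`, `c`, `cprime`, `ab`, `degenerate`.
#' @export
fit_subject_paths <- function(data, x = "x", m = "m", y = "rating",
                              covariates = c("wine", "payment"),
                              drop_middle = TRUE, min_trials = 10) {
  covariates <- intersect(covariates, names(data))
  if (!"subject" %in% names(data)) data$subject <- 1L
  if ("included" %in% names(data)) data <- data[data$included, , drop = FALSE]
  fit_one <- function(d) {
    xv <- d[[x]]; mv <- d[[m]]; yv <- d[[y]]
    keep <- complete.cases(xv, mv, yv)
    if (drop_middle) keep <- keep & xv != 0
    d <- d[keep, , drop = FALSE]
    xv <- xv[keep]; mv <- mv[keep]; yv <- yv[keep]
    if (length(xv) < min_trials) {
      abort(sprintf("subject %s: only %d complete trials (minimum %d).",
                    d$subject[1], length(xv), min_trials))
    }
    if (stats::sd(xv) == 0) {
      abort(sprintf("subject %s: `%s` is constant; paths are not identified.",
                    d$subject[1], x))
    }
    Z <- if (length(covariates)) scale(as.matrix(d[, covariates]),
                                       scale = FALSE) else NULL
    p <- unname(fit_paths_one(xv, mv, yv, Z))
    tibble(subject = d$subject[1], a = p[1], b = p[2], c = p[3],
           cprime = p[4], ab = p[1] * p[2], degenerate = p[5] > 0)
  }
  out <- dplyr::group_modify(dplyr::group_by(data, .data$subject),
                             function(d, g) {
                               d$subject <- g$subject
                               fit_one(d)[, -1]
                             })
  out <- dplyr::ungroup(out)
  structure(out, class = c("path_matrix", class(out)))
}

# Scalar-mediator path fit; Z may be NULL or a centred covariate matrix.
fit_paths_one <- function(xv, mv, yv, Z = NULL) {
  X1 <- cbind(1, xv, Z)
  c_tot <- qr.coef(qr(X1), yv)[2]
  degenerate <- FALSE
  if (stats::sd(mv) < .Machine$double.eps) {
    a <- qr.coef(qr(X1), mv)[2]
    b <- NA_real_; cprime <- NA_real_
    degenerate <- TRUE
  } else {
    a <- qr.coef(qr(X1), mv)[2]
    X3 <- cbind(1, mv, xv, Z)
    cf <- qr.coef(qr(X3), yv)
    b <- cf[2]
    # an aliased direct effect (m exactly collinear with x, the
    # perfect-mediation limit) is attributed entirely to the mediator
    cprime <- if (is.na(cf[3])) 0 else cf[3]
  }
  c(a = unname(a), b = unname(b), c = unname(c_tot), cprime = unname(cprime),
    degenerate = as.numeric(degenerate))
}

# Multi-voxel path fit: M is trials x voxels. Returns list of per-voxel
# vectors a, b, cprime plus scalar c and a degenerate-voxel flag vector.
fit_paths_voxels <- function(xv, M, yv, Z = NULL) {
  X1 <- cbind(1, xv, Z)
  q1 <- qr(X1)
  a <- qr.coef(q1, M)[2, ]
  c_tot <- unname(qr.coef(q1, yv)[2])
  nv <- ncol(M)
  b <- numeric(nv); cprime <- numeric(nv); degenerate <- logical(nv)
  for (v in seq_len(nv)) {
    mv <- M[, v]
    if (stats::sd(mv) < .Machine$double.eps) {
      b[v] <- NA_real_; cprime[v] <- NA_real_; degenerate[v] <- TRUE
      next
    }
    cf <- .lm.fit(cbind(1, mv, xv, Z), yv)$coefficients
    b[v] <- cf[2]; cprime[v] <- cf[3]
  }
  list(a = unname(a), b = b, c = c_tot, cprime = cprime,
       degenerate = degenerate)
}

#' Decompose the group indirect effect
#'
#' Splits the group-mean indirect effect into the product of mean paths and
#' the between-subject covariance of the paths:
#' `mean(a * b) = mean(a) * mean(b) + cov(a, b)`. The covariance uses the
#' population (1/n) denominator, which makes the identity exact.
#'
#' @param paths A `path_matrix` from [fit_subject_paths()], or any data
#'   frame with columns `a`, `b`, `ab`.
#' @return A one-row tibble: `mean_ab`, `prod_means`, `cov_ab`, `n_subjects`.
#' @export
group_decompose <- function(paths) {
  if (nrow(paths) < 2) abort("need at least 2 subjects.")
  a <- paths$a; b <- paths$b
  ab <- if ("ab" %in% names(paths)) paths$ab else a * b
  n <- length(a)
  cov_ab <- mean(a * b) - mean(a) * mean(b)   # population (1/n) covariance
  tibble(mean_ab = mean(ab), prod_means = mean(a) * mean(b),
         cov_ab = cov_ab, n_subjects = n)
}

#' Bootstrap inference on subject-level path coefficients
#'
#' Resamples whole subject rows of the `[a, b, c, c', ab]` matrix with
#' replacement and computes the mean of each column per resample; for the
#' indirect effect the resample statistic `mean(ab)` equals
#' `mean(a) * mean(b) + cov(a, b)` within the resample, i.e. it carries the
#' covariance component of the group effect. Two-tailed p-values are read
#' off the bootstrap distribution as
#' `p = 2 * min(Pr(theta* <= 0), Pr(theta* >= 0))` (ties at zero counted on
#' both sides), floored at `2 / n_boot`; confidence intervals are
#' percentile intervals.
#'
#' @param paths A `path_matrix` (columns `a`, `b`, `c`, `cprime`, `ab`).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param ci_level Confidence level (default 0.95).
#' @return An object of class `mediation_boot`: tibble with one row per
#'   path (`a`, `b`, `c`, `cprime`, `ab`) and columns `estimate`,
#'   `ci_lower`, `ci_upper`, `p`, `degenerate`; attributes `n_boot`,
#'   `n_subjects`, `seed`.
#' @export
bootstrap_inference <- function(paths, n_boot = 10000, seed = NULL,
                                ci_level = 0.95) {
  paths <- paths[!vapply(seq_len(nrow(paths)), function(i)
    anyNA(paths[i, c("a", "b", "cprime")]), logical(1)), , drop = FALSE]
  n <- nrow(paths)
  if (n < 5) abort("need at least 5 non-degenerate subjects to bootstrap.")
  cols <- c("a", "b", "c", "cprime", "ab")
  P <- as.matrix(paths[, cols])
  alpha <- 1 - ci_level
  with_seed_(seed, {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
    res <- purrr::map_dfr(cols, function(cl) {
      v <- P[, cl]
      th <- rowMeans(matrix(v[idx], n_boot, n))
      zero_width <- (max(th) - min(th)) < 1e-14
      p <- 2 * min(mean(th <= 0), mean(th >= 0))
      p <- min(1, max(p, 2 / n_boot))
      ci <- unname(quantile(th, c(alpha / 2, 1 - alpha / 2)))
      tibble(path = cl, estimate = mean(v), ci_lower = ci[1],
             ci_upper = ci[2], p = p, degenerate = zero_width)
    })
    structure(res, n_boot = n_boot, n_subjects = n, seed = seed,
              ci_level = ci_level,
              class = c("mediation_boot", class(res)))
  })
}

#' Two-level mediation with bootstrap inference
#'
#' Convenience wrapper chaining [fit_subject_paths()],
#' [group_decompose()] and [bootstrap_inference()].
#'
#' @inheritParams fit_subject_paths
#' @inheritParams bootstrap_inference
#' @return An object of class `mediation_fit`: list with `paths` (the
#'   subject-level path matrix), `decomposition`, and `boot`.
#' @examples
#' study <- simulate_study(n_subjects = 12, seed = 7)
#' fit <- mediate(study$trials, n_boot = 500, seed = 1)
#' tidy(fit)
#' @export
mediate <- function(data, x = "x", m = "m", y = "rating",
                    covariates = c("wine", "payment"), drop_middle = TRUE,
                    n_boot = 10000, seed = NULL, ci_level = 0.95) {
  paths <- fit_subject_paths(data, x = x, m = m, y = y,
                             covariates = covariates,
                             drop_middle = drop_middle)
  structure(
    list(paths = paths,
         decomposition = group_decompose(paths),
         boot = bootstrap_inference(paths, n_boot = n_boot, seed = seed,
                                    ci_level = ci_level)),
    class = "mediation_fit"
  )
}

#' Voxelwise two-level mediation maps
#'
#' Runs the subject-level path regressions and the subject-resampling
#' bootstrap at every voxel of a beta-series. Covariates of no interest
#' enter every within-subject regression. Subjects with a degenerate fit at
#' a voxel (constant mediator) are dropped at that voxel only; the count is
#' recorded.
#'
#' @param subjects A list with one element per subject, each a list with
#'   `x` (trial contrast codes), `m` (trials x voxels mediator matrix),
#'   `y` (trial ratings), optional `covariates` (trials x q matrix) and
#'   optional `included` (logical per trial).
#' @param n_boot Bootstrap resamples per voxel (default 1000 for maps).
#' @param seed Integer seed.
#' @param grid Optional [volume_grid()] describing the voxel layout.
#' @param drop_middle Drop `x == 0` trials (middle price level).
#' @return An object of class `mediation_maps`: long tibble with columns
#'   `path`, `voxel`, `estimate`, `ci_lower`, `ci_upper`, `p`; attributes
#'   `grid`, `n_subjects`, `n_boot`, `dropped` (subject x voxel degenerate
#'   count).
#' @export
voxelwise_mediation <- function(subjects, n_boot = 1000, seed = NULL,
                                grid = NULL, drop_middle = TRUE,
                                ci_level = 0.95) {
  n_sub <- length(subjects)
  if (n_sub < 5) abort("need at least 5 subjects.")
  nv <- ncol(subjects[[1]]$m)
  per_sub <- lapply(subjects, function(s) {
    keep <- rep(TRUE, length(s$x))
    if (!is.null(s$included)) keep <- keep & s$included
    if (drop_middle) keep <- keep & s$x != 0
    xv <- s$x[keep]; yv <- s$y[keep]
    M <- s$m[keep, , drop = FALSE]
    if (ncol(M) != nv) abort("subjects do not share the voxel grid.")
    Z <- if (!is.null(s$covariates))
      scale(as.matrix(s$covariates)[keep, , drop = FALSE], scale = FALSE)
    else NULL
    fit_paths_voxels(xv, M, yv, Z)
  })
  A <- do.call(rbind, lapply(per_sub, `[[`, "a"))
  B <- do.call(rbind, lapply(per_sub, `[[`, "b"))
  Cp <- do.call(rbind, lapply(per_sub, `[[`, "cprime"))
  Cc <- matrix(vapply(per_sub, `[[`, numeric(1), "c"), n_sub, nv)
  AB <- A * B
  dropped <- colSums(is.na(B))
  alpha <- 1 - ci_level
  with_seed_(seed, {
    idx <- matrix(sample.int(n_sub, n_boot * n_sub, replace = TRUE),
                  n_boot, n_sub)
    W <- matrix(0, n_boot, n_sub)
    for (r in seq_len(n_boot)) {
      tb <- tabulate(idx[r, ], nbins = n_sub)
      W[r, ] <- tb
    }
    boot_path <- function(P) {
      # NA-aware subject-resampling means: per voxel, weights renormalized
      # over the subjects that are non-degenerate there.
      P0 <- P; P0[is.na(P)] <- 0
      ok <- !is.na(P)
      num <- W %*% P0
      den <- W %*% ok
      num / pmax(den, 1)
    }
    build <- function(name, P) {
      TH <- boot_path(P)
      est <- colMeans(P, na.rm = TRUE)
      p <- vapply(seq_len(nv), function(v) {
        th <- TH[, v]
        pv <- 2 * min(mean(th <= 0), mean(th >= 0))
        min(1, max(pv, 2 / n_boot))
      }, numeric(1))
      cis <- apply(TH, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2))
      tibble(path = name, voxel = seq_len(nv), estimate = est,
             ci_lower = cis[1, ], ci_upper = cis[2, ], p = p)
    }
    res <- dplyr::bind_rows(
      build("a", A), build("b", B), build("ab", AB),
      build("cprime", Cp), build("c", Cc)
    )
    structure(res, grid = grid, n_subjects = n_sub, n_boot = n_boot,
              seed = seed, dropped = dropped,
              class = c("mediation_maps", class(res)))
  })
}

#' Classify the mediation pattern at a voxel
#'
#' Partial mediation: both the indirect effect `ab` and the direct effect
#' `c'` are significant; full mediation: `ab` significant but `c'` not;
#' otherwise none.
#'
#' @param maps A `mediation_maps` or `mediation_fit` object (or the tibble
#'   of a `mediation_boot`).
#' @param voxel Voxel index (required for maps).
#' @param alpha Significance level (default 0.05).
#' @return One of `"full"`, `"partial"`, `"none"`.
#' @export
classify_mediation <- function(maps, voxel = NULL, alpha = 0.05) {
  tb <- if (inherits(maps, "mediation_fit")) maps$boot else maps
  if (!is.null(voxel) && "voxel" %in% names(tb)) tb <- tb[tb$voxel == voxel, ]
  p_ab <- tb$p[tb$path == "ab"]
  p_cp <- tb$p[tb$path == "cprime"]
  if (length(p_ab) != 1 || length(p_cp) != 1) {
    abort("need bootstrap results for paths 'ab' and 'cprime' (supply `voxel` for maps).")
  }
  if (p_ab < alpha && p_cp < alpha) "partial"
  else if (p_ab < alpha) "full"
  else "none"
}
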