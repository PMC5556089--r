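#' Average a volume within a spherical ROI
#'
#' Unweighted mean over all voxels whose centre lies within `radius_mm` of
#' `center_mm` — the operation used to extract a per-subject moderator from
#' an independent task's beta image.
#'
#' @param volume 3-D numeric array on `grid`.
#' @param center_mm ROI centre in world mm.
#' @param radius_mm Sphere radius in mm (default 10).
#' @param grid A [volume_grid()]; defaults to the volume's `grid` attribute.
#' @return The in-sphere mean, a single number.
#' @export
sphere_average <- function(volume, center_mm, radius_mm = 10, grid = NULL) {
  grid <- grid %||% attr(volume, "grid")
  if (is.null(grid)) abort("a `volume_grid` is required.")
  sph <- make_sphere(grid, center_mm, radius_mm)
  mean(volume[sph$voxel])
}

#' Second-level moderated mediation
#'
#' Tests whether a subject-level moderator (e.g. value-system sensitivity
#' measured in an independent task) scales a mediation path: the moderator
#' is mean-centred and the chosen path coefficient is regressed on it
#' across subjects, `path_i = gamma0 + gamma1 * w_i + e_i`. Because `w` is
#' centred, `gamma0` estimates the average path at the mean moderator
#' level. Inference comes from a pairs bootstrap over subjects: confidence
#' intervals are percentile intervals, while two-tailed p-values are
#' studentized — the estimate divided by its bootstrap standard error,
#' referred to a t distribution on `n - 2` degrees of freedom. (A raw
#' percentile p is anti-conservative at second-level sample sizes around
#' 15-20; the studentized form keeps the nominal level.)
#'
#' @param paths A `path_matrix` from [fit_subject_paths()] (must have a
#'   `subject` column).
#' @param moderators A tibble with columns `subject` and `w` (one finite
#'   value per subject).
#' @param path Which path to moderate: `"a"` (default), `"b"` or `"ab"`.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param ci_level Confidence level for the percentile CI.
#' @param min_subjects Minimum subjects with both values (default 8).
#' @return An object of class `moderation_fit`: tibble with rows `gamma0`
#'   and `gamma1` (`estimate`, `ci_lower`, `ci_upper`, `p`); attributes
#'   `path`, `n_subjects`, `n_boot`.
#' @export
moderate_path <- function(paths, moderators, path = c("a", "b", "ab"),
                          n_boot = 10000, seed = NULL, ci_level = 0.95,
                          min_subjects = 8) {
  path <- match.arg(path)
  d <- dplyr::inner_join(
    paths[, c("subject", path)],
    moderators[, c("subject", "w")],
    by = "subject"
  )
  d <- d[is.finite(d[[path]]) & is.finite(d$w), , drop = FALSE]
  n <- nrow(d)
  if (n < min_subjects) {
    abort(sprintf("only %d subjects with both a '%s' coefficient and a moderator (minimum %d).",
                  n, path, min_subjects))
  }
  if (stats::sd(d$w) < .Machine$double.eps) {
    abort("moderator `w` has zero variance.")
  }
  wc <- d$w - mean(d$w)
  pv <- d[[path]]
  ols <- function(p, w) {
    g1 <- sum(w * p) / sum(w * w)
    c(g0 = mean(p) - g1 * mean(w), g1 = g1)
  }
  est <- ols(pv, wc)
  alpha <- 1 - ci_level
  with_seed_(seed, {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
    g1s <- numeric(n_boot); g0s <- numeric(n_boot)
    for (r in seq_len(n_boot)) {
      ii <- idx[r, ]
      w <- wc[ii]; p <- pv[ii]
      vw <- stats::var(w)
      if (vw < .Machine$double.eps) { g1s[r] <- NA; g0s[r] <- mean(p); next }
      g1 <- sum((w - mean(w)) * p) / sum((w - mean(w))^2)
      g1s[r] <- g1
      g0s[r] <- mean(p) - g1 * mean(w)
    }
    g1s <- g1s[is.finite(g1s)]
    pboot <- function(th, hat) {
      se <- stats::sd(th)
      if (se < .Machine$double.eps) return(if (hat == 0) 1 else 2 / length(th))
      2 * pt(-abs(hat / se), df = n - 2)
    }
    res <- tibble(
      term = c("gamma0", "gamma1"),
      estimate = unname(c(est["g0"], est["g1"])),
      ci_lower = unname(c(quantile(g0s, alpha / 2), quantile(g1s, alpha / 2))),
      ci_upper = unname(c(quantile(g0s, 1 - alpha / 2),
                          quantile(g1s, 1 - alpha / 2))),
      p = c(pboot(g0s, est["g0"]), pboot(g1s, est["g1"]))
    )
    structure(res, path = path, n_subjects = n, n_boot = n_boot, seed = seed,
              class = c("moderation_fit", class(res)))
  })
}
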