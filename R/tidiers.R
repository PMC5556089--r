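# broom-style tidiers and print methods for the package's fitted objects.

#' @export
tidy.mediation_fit <- function(x, ...) {
  as_tibble(x$boot)
}

#' @export
glance.mediation_fit <- function(x, ...) {
  dplyr::bind_cols(
    x$decomposition,
    tibble(n_boot = attr(x$boot, "n_boot"),
           classification = classify_mediation(x))
  )
}

#' @export
tidy.mediation_boot <- function(x, ...) as_tibble(x)

#' @export
tidy.mediation_maps <- function(x, ...) as_tibble(x)

#' @export
glance.mediation_maps <- function(x, ...) {
  tibble(n_subjects = attr(x, "n_subjects"),
         n_voxels = length(unique(x$voxel)),
         n_boot = attr(x, "n_boot"),
         dropped_fits = sum(attr(x, "dropped")))
}

#' @export
tidy.rating_lmm <- function(x, ...) x$fixed

#' @export
glance.rating_lmm <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_fixed = x$n_fixed, df = x$df,
         logLik = x$logLik, deviance = x$deviance, AIC = x$AIC, BIC = x$BIC,
         ranef_sd = x$ranef_sd, sigma = x$sigma)
}

#' @export
tidy.moderation_fit <- function(x, ...) as_tibble(x)

#' @export
glance.moderation_fit <- function(x, ...) {
  tibble(path = attr(x, "path"), n_subjects = attr(x, "n_subjects"),
         n_boot = attr(x, "n_boot"))
}

#' @export
tidy.fir_fit <- function(x, ...) as_tibble(x)

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Two-level mediation fit (%d subjects, %d bootstrap resamples)\n",
              nrow(x$paths), attr(x$boot, "n_boot")))
  dc <- x$decomposition
  cat(sprintf("  group indirect effect mean(ab) = %.4f  [mean(a)*mean(b) = %.4f, cov(a,b) = %.4f]\n",
              dc$mean_ab, dc$prod_means, dc$cov_ab))
  print(as.data.frame(x$boot), digits = 4, row.names = FALSE)
  cat(sprintf("  classification: %s mediation\n", classify_mediation(x)))
  invisible(x)
}

#' @export
print.rating_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept mixed model: %d observations, %d fixed terms, df = %d\n",
              x$n_obs, x$n_fixed, x$df))
  cat(sprintf("  logLik %.1f  deviance %.1f  AIC %.0f  BIC %.0f\n",
              x$logLik, x$deviance, x$AIC, x$BIC))
  cat(sprintf("  random intercept s.d. %.3f, residual s.d. %.3f\n",
              x$ranef_sd, x$sigma))
  print(as.data.frame(x$fixed), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Clusters for path '%s' (p < %g, extent >= %d, %d-connectivity)\n",
              x$path, x$p_threshold, x$k, x$connectivity))
  print(as.data.frame(x$clusters), digits = 4, row.names = FALSE)
  invisible(x)
}
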