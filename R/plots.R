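# ggplot2 visualization helpers.

#' Plot the canonical HRF
#'
#' @param hrf An [hrf_spec()].
#' @param dt Sampling step in seconds.
#' @return A ggplot.
#' @export
plot_hrf <- function(hrf = hrf_spec(), dt = 0.1) {
  t <- seq(0, hrf$length_s, by = dt)
  ggplot2::ggplot(tibble(time_s = t, response = eval_hrf(hrf, t)),
                  ggplot2::aes(x = .data$time_s, y = .data$response)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "peristimulus time (s)", y = "response (peak = 1)",
                  title = "Canonical double-gamma HRF") +
    ggplot2::theme_minimal()
}

#' Plot mean ratings by price cue
#'
#' Bar graph of the mean pleasantness rating per price level with standard
#' errors of the mean, the standard behavioral display for this design.
#'
#' @param trials Trial tibble with `price` and `rating` (and optionally
#'   `subject` for subject-wise means first).
#' @return A ggplot.
#' @export
plot_ratings <- function(trials) {
  d <- trials[is.finite(trials$rating), ]
  if ("subject" %in% names(d)) {
    d <- dplyr::summarise(dplyr::group_by(d, .data$subject, .data$price),
                          rating = mean(.data$rating), .groups = "drop")
  }
  s <- dplyr::summarise(dplyr::group_by(d, .data$price),
                        mean = mean(.data$rating),
                        sem = stats::sd(.data$rating) / sqrt(dplyr::n()),
                        .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$price), y = .data$mean)) +
    ggplot2::geom_col(fill = "#74a9cf", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = "price cue level", y = "experienced pleasantness") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mediation_fit <- function(object, ...) {
  tb <- object$boot
  tb$path <- factor(tb$path, levels = rev(c("a", "b", "ab", "c", "cprime")))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$estimate, y = .data$path)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.15) +
    ggplot2::geom_point(size = 2, colour = "#2c7fb8") +
    ggplot2::labs(x = "path coefficient (bootstrap 95% CI)", y = NULL,
                  title = "Two-level mediation paths") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fir_fit <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$estimate,
                                       colour = .data$condition,
                                       fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - .data$se,
                                      ymax = .data$estimate + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "peristimulus time (s)", y = "FIR estimate",
                  title = "Deconvolved time course") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mediation_maps <- function(object, path = "ab", slices = NULL, ...) {
  grid <- attr(object, "grid")
  if (is.null(grid)) abort("maps carry no `volume_grid`; cannot plot slices.")
  tb <- object[object$path == path, ]
  ijk <- voxel_to_ijk(tb$voxel, grid$dim)
  d <- tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
              logp = -log10(tb$p), estimate = tb$estimate)
  slices <- slices %||% unique(round(seq(1, grid$dim[3], length.out = 4)))
  d <- d[d$k %in% slices, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j,
                                  fill = .data$logp)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Bootstrap p map, path '%s'", path)) +
    ggplot2::theme_minimal()
}
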