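# Pipeline stages chaining the modules behind a single JSON-serializable
# configuration with per-stage seeds. Each stage is idempotent given the
# same config and inputs; `run_report()` assembles the results manifest.

#' Default pipeline configuration
#'
#' A complete, runnable configuration at a desk-scale grid: the full
#' 108-trial design per subject, a modest subject count and voxel grid so
#' that the whole pipeline completes in minutes on one CPU. Every
#' stochastic stage has its own seed.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param n_subjects Number of simulated subjects.
#' @param seed Base seed; per-stage seeds are derived from it.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(out_dir = file.path(tempdir(), "brainmediate-run"),
                           n_subjects = 12, seed = 42) {
  structure(list(
    out_dir = out_dir,
    n_subjects = n_subjects,
    design = list(reps_per_condition = 18, n_runs = 3, tr_s = 2.5,
                  tasting_duration_s = 3),
    sim = list(a_mean = 0.5, a_sd = 0.3, b_mean = 0.4, b_sd = 0.26,
               ab_cov = 0.05, cprime_mean = 0.1, cprime_sd = 0.05,
               mediator_noise_sd = 1, rating_noise_sd = 1,
               grid_dim = c(8, 8, 8), voxel_size_mm = 2,
               n_mediator_voxels = 5, drift_amplitude = 1,
               ar_phi = 0.3, ar_sd = 1, motion_leak = 0.5,
               x_coding = "extremes"),
    glm = list(duration_s = 3, vif_threshold = 2.5),
    mediation = list(n_boot = 5000, p_threshold = 0.001, cluster_k = 5,
                     connectivity = 26, svc_radius_mm = 6, svc_alpha = 0.05,
                     roi_centers = NULL),
    moderation = list(path = "a", n_boot = 2000),
    seeds = list(simulate = child_seed(seed, 1), mediate = child_seed(seed, 2),
                 moderate = child_seed(seed, 3))
  ), class = "run_config")
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip through JSON.
#'
#' @param config A `run_config` list.
#' @param path JSON file path.
#' @return `read_config()`: the `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_config")
}

cfg_design_spec <- function(config) {
  d <- config$design
  design_spec(reps_per_condition = d$reps_per_condition %||% 18,
              n_runs = d$n_runs %||% 3,
              tasting_duration_s = d$tasting_duration_s %||% 3,
              tr_s = d$tr_s %||% 2.5)
}

cfg_sim_config <- function(config) {
  do.call(sim_config, config$sim)
}

require_stage <- function(config, subdir, stage) {
  p <- file.path(config$out_dir, subdir)
  if (!dir.exists(p)) {
    abort(sprintf("missing upstream artifacts in '%s': run the '%s' stage first.",
                  p, stage))
  }
  p
}

sub_tag <- function(i) sprintf("sub-%02d", i)

#' Pipeline stage: simulate a study
#'
#' Generates per-subject designs, parameters, trial data and BOLD runs, and
#' writes events TSVs, NIfTI volumes, motion traces, the moderator table
#' and a ground-truth JSON under `out_dir/simulate`.
#'
#' @param config A `run_config` (see [default_config()]) or path to one.
#' @return The simulate directory, invisibly.
#' @export
run_simulate <- function(config) {
  config <- as_run_config(config)
  spec <- cfg_design_spec(config)
  sim <- cfg_sim_config(config)
  out <- file.path(config$out_dir, "simulate")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seeds$simulate
  with_seed_(seed %||% 1L, {
    params <- draw_subject_params(sim, config$n_subjects)
    if (is.null(sim$mediator_voxels)) {
      # mediating regions are common across the group: fix them once
      sim$mediator_voxels <- sort(sample.int(prod(sim$grid_dim),
                                             sim$n_mediator_voxels))
    }
    truth <- list(seed = seed, n_subjects = config$n_subjects,
                  a_mean = sim$a_mean, b_mean = sim$b_mean,
                  ab_cov = sim$ab_cov,
                  true_group_ab = sim$a_mean * sim$b_mean + sim$ab_cov,
                  grid_dim = sim$grid_dim,
                  mediator_voxels = sim$mediator_voxels)
    for (i in seq_len(config$n_subjects)) {
      d <- generate_design(spec)
      td <- simulate_trial_data(d, params[i, ], sim)
      bold <- simulate_bold(td, td$m, sim, spec = spec)
      write_events(td, file.path(out, paste0(sub_tag(i), "_events.tsv")),
                   duration_s = spec$tasting_duration_s)
      for (r in seq_along(bold$runs)) {
        # data arrives volumes x voxels; store voxels-major as x,y,z,t
        arr <- array(t(bold$runs[[r]]$data),
                     dim = c(sim$grid_dim, bold$runs[[r]]$n_vols))
        write_nifti(arr, file.path(out, sprintf("%s_run-%d_bold.nii",
                                                sub_tag(i), r)),
                    grid = bold$grid, datatype = "float32", tr_s = spec$tr_s)
        write_motion(bold$motion[[r]],
                     file.path(out, sprintf("%s_run-%d_motion.txt",
                                            sub_tag(i), r)))
      }
    }
    readr::write_tsv(tibble(subject = params$subject, w = params$moderator_w),
                     file.path(out, "moderators.tsv"))
    readr::write_tsv(params, file.path(out, "subject_params.tsv"))
    write_manifest(truth, file.path(out, "truth.json"))
  })
  invisible(out)
}

#' Pipeline stage: single-trial GLM
#'
#' Reads the simulated runs, builds the single-trial design with the
#' 24-regressor motion nuisance set, estimates the beta-series per subject
#' and writes beta NIfTIs (trial as 4th dimension) plus per-trial QC tables
#' under `out_dir/glm`.
#'
#' @inheritParams run_simulate
#' @export
run_glm <- function(config) {
  config <- as_run_config(config)
  sim_dir <- require_stage(config, "simulate", "simulate")
  spec <- cfg_design_spec(config)
  sim <- cfg_sim_config(config)
  out <- file.path(config$out_dir, "glm")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(config$n_subjects)) {
    trials <- read_events(file.path(sim_dir, paste0(sub_tag(i), "_events.tsv")))
    runs <- sort(unique(trials$run))
    bold_runs <- list(); motion <- list()
    for (r in seq_along(runs)) {
      vol <- read_nifti(file.path(sim_dir, sprintf("%s_run-%d_bold.nii",
                                                   sub_tag(i), r)))
      dm <- dim(vol)
      bold_runs[[r]] <- t(matrix(vol, prod(dm[1:3]), dm[4]))
      motion[[r]] <- read_motion(file.path(sim_dir,
                                           sprintf("%s_run-%d_motion.txt",
                                                   sub_tag(i), r)))
    }
    run_lengths <- vapply(bold_runs, nrow, integer(1))
    des <- build_single_trial_design(trials, tr_s = spec$tr_s,
                                     run_lengths = run_lengths,
                                     duration_s = config$glm$duration_s %||% 3,
                                     motion = motion)
    bs <- estimate_betas(do.call(rbind, bold_runs), des,
                         vif_threshold = config$glm$vif_threshold %||% 2.5)
    grid <- volume_grid(sim$grid_dim, voxel_size_mm = sim$voxel_size_mm)
    beta_arr <- array(t(bs$betas), dim = c(sim$grid_dim, nrow(bs$betas)))
    write_nifti(beta_arr, file.path(out, paste0(sub_tag(i), "_betas.nii")),
                grid = grid, datatype = "float32")
    readr::write_tsv(bs$qc, file.path(out, paste0(sub_tag(i), "_qc.tsv")))
  }
  invisible(out)
}

#' Pipeline stage: voxelwise mediation
#'
#' Assembles per-subject beta-series, ratings and contrast codes, runs the
#' voxelwise two-level mediation with bootstrap inference, thresholds and
#' clusters the indirect-effect map, applies small-volume correction, and
#' writes effect/p NIfTIs, cluster tables and a JSON manifest under
#' `out_dir/mediation`.
#'
#' @inheritParams run_simulate
#' @param n_boot Optional override of `config$mediation$n_boot`.
#' @return The `mediation_maps` object, invisibly.
#' @export
run_mediate <- function(config, n_boot = NULL) {
  config <- as_run_config(config)
  sim_dir <- require_stage(config, "simulate", "simulate")
  glm_dir <- require_stage(config, "glm", "glm")
  sim <- cfg_sim_config(config)
  out <- file.path(config$out_dir, "mediation")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  n_boot <- n_boot %||% config$mediation$n_boot %||% 1000
  grid <- volume_grid(sim$grid_dim, voxel_size_mm = sim$voxel_size_mm)
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    trials <- read_events(file.path(sim_dir, paste0(sub_tag(i), "_events.tsv")))
    vol <- read_nifti(file.path(glm_dir, paste0(sub_tag(i), "_betas.nii")))
    dm <- dim(vol)
    betas <- t(matrix(vol, prod(dm[1:3]), dm[4]))
    qc <- readr::read_tsv(file.path(glm_dir, paste0(sub_tag(i), "_qc.tsv")),
                          show_col_types = FALSE, progress = FALSE)
    list(x = price_contrast(trials$price, max(trials$price), sim$x_coding),
         m = betas, y = trials$rating,
         covariates = cbind(wine = trials$wine, payment = trials$payment),
         included = qc$included)
  })
  maps <- voxelwise_mediation(subjects, n_boot = n_boot,
                              seed = config$seeds$mediate, grid = grid)
  for (pth in unique(maps$path)) {
    tb <- maps[maps$path == pth, ]
    evol <- array(0, grid$dim); pvol <- array(1, grid$dim)
    evol[tb$voxel] <- tb$estimate; pvol[tb$voxel] <- tb$p
    write_nifti(evol, file.path(out, sprintf("path-%s_effect.nii", pth)),
                grid = grid, datatype = "float32")
    write_nifti(pvol, file.path(out, sprintf("path-%s_p.nii", pth)),
                grid = grid, datatype = "float32")
  }
  centers <- config$mediation$roi_centers
  if (is.null(centers)) {
    truth <- read_manifest(file.path(sim_dir, "truth.json"))
    ctr <- voxel_to_mm(grid, voxel_to_ijk(truth$mediator_voxels[1], grid$dim))
    centers <- list(planted = as.numeric(ctr))
  }
  svc <- purrr::map_dfr(c("a", "b", "ab"), function(pth) {
    dplyr::mutate(
      small_volume_correct(maps, path = pth, centers_mm = centers,
                           radius_mm = config$mediation$svc_radius_mm %||% 10,
                           alpha = config$mediation$svc_alpha %||% 0.05,
                           grid = grid),
      path = pth, .before = 1)
  })
  readr::write_tsv(svc, file.path(out, "svc.tsv"))
  cluster_tables <- purrr::map_dfr(c("a", "b", "ab"), function(pth) {
    cl <- threshold_and_cluster(maps, path = pth,
                                p_threshold = config$mediation$p_threshold %||% 0.001,
                                k = config$mediation$cluster_k %||% 5,
                                connectivity = config$mediation$connectivity %||% 26,
                                grid = grid)
    dplyr::mutate(cl$clusters, path = pth, .before = 1)
  })
  readr::write_tsv(cluster_tables, file.path(out, "clusters.tsv"))
  write_manifest(
    list(n_subjects = config$n_subjects, n_boot = n_boot,
         seed = config$seeds$mediate,
         p_threshold = config$mediation$p_threshold %||% 0.001,
         cluster_k = config$mediation$cluster_k %||% 5,
         connectivity = config$mediation$connectivity %||% 26,
         svc_radius_mm = config$mediation$svc_radius_mm %||% 10,
         roi_centers = centers,
         dropped_fits = sum(attr(maps, "dropped")),
         n_clusters_ab = sum(cluster_tables$path == "ab")),
    file.path(out, "manifest.json"))
  invisible(maps)
}

#' Pipeline stage: second-level moderation
#'
#' Averages each subject's beta-series within the first ROI sphere, fits
#' the path regressions on the ROI mediator, and tests whether the chosen
#' path scales with the per-subject moderator.
#'
#' @inheritParams run_simulate
#' @return The `moderation_fit`, invisibly.
#' @export
run_moderate <- function(config) {
  config <- as_run_config(config)
  sim_dir <- require_stage(config, "simulate", "simulate")
  glm_dir <- require_stage(config, "glm", "glm")
  med_dir <- require_stage(config, "mediation", "mediate")
  sim <- cfg_sim_config(config)
  out <- file.path(config$out_dir, "moderation")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  grid <- volume_grid(sim$grid_dim, voxel_size_mm = sim$voxel_size_mm)
  manifest <- read_manifest(file.path(med_dir, "manifest.json"))
  ctr <- as.numeric(manifest$roi_centers[[1]])
  radius <- manifest$svc_radius_mm %||% 10
  sph <- make_sphere(grid, ctr, radius)
  rows <- purrr::map_dfr(seq_len(config$n_subjects), function(i) {
    trials <- read_events(file.path(sim_dir, paste0(sub_tag(i), "_events.tsv")))
    vol <- read_nifti(file.path(glm_dir, paste0(sub_tag(i), "_betas.nii")))
    dm <- dim(vol)
    betas <- t(matrix(vol, prod(dm[1:3]), dm[4]))
    qc <- readr::read_tsv(file.path(glm_dir, paste0(sub_tag(i), "_qc.tsv")),
                          show_col_types = FALSE, progress = FALSE)
    d <- tibble(subject = i,
                x = price_contrast(trials$price, max(trials$price), sim$x_coding),
                m = rowMeans(betas[, sph$voxel, drop = FALSE]),
                rating = trials$rating,
                wine = trials$wine, payment = trials$payment,
                included = qc$included)
    fit_subject_paths(d)
  })
  moderators <- readr::read_tsv(file.path(sim_dir, "moderators.tsv"),
                                show_col_types = FALSE, progress = FALSE)
  fit <- moderate_path(rows, moderators,
                       path = config$moderation$path %||% "a",
                       n_boot = config$moderation$n_boot %||% 10000,
                       seed = config$seeds$moderate)
  readr::write_tsv(as_tibble(fit), file.path(out, "moderation.tsv"))
  write_manifest(list(path = attr(fit, "path"),
                      n_subjects = attr(fit, "n_subjects"),
                      n_boot = attr(fit, "n_boot"),
                      roi_center = ctr, radius_mm = radius,
                      gamma1 = fit$estimate[fit$term == "gamma1"],
                      gamma1_p = fit$p[fit$term == "gamma1"]),
                 file.path(out, "manifest.json"))
  invisible(fit)
}

#' Pipeline stage: behavioral mixed model
#'
#' Fits the random-intercept mixed model to the simulated ratings of all
#' subjects and writes the fixed-effect table and model summary.
#'
#' @inheritParams run_simulate
#' @return The `rating_lmm`, invisibly.
#' @export
run_behavior <- function(config) {
  config <- as_run_config(config)
  sim_dir <- require_stage(config, "simulate", "simulate")
  out <- file.path(config$out_dir, "behavior")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  trials <- purrr::map_dfr(seq_len(config$n_subjects), function(i) {
    d <- read_events(file.path(sim_dir, paste0(sub_tag(i), "_events.tsv")))
    d$subject <- i
    d
  })
  fit <- fit_rating_lmm(trials)
  readr::write_tsv(tidy(fit), file.path(out, "fixed_effects.tsv"))
  write_manifest(as.list(glance(fit)), file.path(out, "manifest.json"))
  invisible(fit)
}

#' Pipeline stage: assemble the results report
#'
#' Collects the stage manifests into one JSON manifest plus a
#' human-readable summary listing, per path, the surviving clusters
#' (region label, size, peak coordinates, statistic).
#'
#' @inheritParams run_simulate
#' @return Path of the report directory, invisibly.
#' @export
run_report <- function(config) {
  config <- as_run_config(config)
  med_dir <- require_stage(config, "mediation", "mediate")
  out <- file.path(config$out_dir, "report")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(mediation = read_manifest(file.path(med_dir, "manifest.json")))
  for (stage in c("moderation", "behavior")) {
    p <- file.path(config$out_dir, stage, "manifest.json")
    if (file.exists(p)) manifest[[stage]] <- read_manifest(p)
  }
  truth_p <- file.path(config$out_dir, "simulate", "truth.json")
  if (file.exists(truth_p)) manifest$truth <- read_manifest(truth_p)
  write_manifest(manifest, file.path(out, "manifest.json"))
  clusters <- readr::read_tsv(file.path(med_dir, "clusters.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  svc <- readr::read_tsv(file.path(med_dir, "svc.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  lines <- c("Mediation results", "=================", "")
  for (pth in c("a", "b", "ab")) {
    lines <- c(lines, sprintf("Path %s clusters (size, peak mm, estimate, min p):", pth))
    cl <- clusters[clusters$path == pth, , drop = FALSE]
    if (nrow(cl) == 0) lines <- c(lines, "  (none above threshold)")
    else for (r in seq_len(nrow(cl))) {
      lines <- c(lines, sprintf("  %3d voxels  [%+.0f %+.0f %+.0f]  %8.4f  p=%.4g",
                                cl$n_voxels[r], cl$peak_mm_x[r], cl$peak_mm_y[r],
                                cl$peak_mm_z[r], cl$peak_estimate[r], cl$min_p[r]))
    }
    sv <- svc[svc$path == pth, , drop = FALSE]
    for (r in seq_len(nrow(sv))) {
      lines <- c(lines, sprintf("  SVC %-8s p_corrected=%.4g %s", sv$roi[r],
                                sv$p_corrected[r],
                                ifelse(sv$significant[r], "*", "")))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, file.path(out, "summary.txt"))
  invisible(out)
}

#' Run the full pipeline
#'
#' `simulate`, `glm`, `mediate`, `moderate`, `behavior`, `report`, in
#' order.
#'
#' @inheritParams run_simulate
#' @return The report directory, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- as_run_config(config)
  run_simulate(config)
  run_glm(config)
  run_mediate(config)
  run_moderate(config)
  run_behavior(config)
  run_report(config)
}

as_run_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config")) class(config) <- "run_config"
  config
}
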