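# Shared fixtures, all built in code at test time.

# Compact design: 2 runs x 18 trials (36 trials), full factorial balance.
small_spec <- function() design_spec(reps_per_condition = 6, n_runs = 2)

# Noise-free simulation config on a tiny grid.
noise_free_config <- function(...) {
  sim_config(mediator_noise_sd = 0, rating_noise_sd = 0,
             drift_amplitude = 0, ar_sd = 0, motion_leak = 0,
             grid_dim = c(4, 4, 4), n_mediator_voxels = 3, ...)
}

# Random subject-level path matrix (no model structure; for identities).
random_path_matrix <- function(n, seed = NULL) {
  gen <- function() {
    a <- rnorm(n); b <- rnorm(n)
    tibble::tibble(subject = seq_len(n), a = a, b = b,
                   c = rnorm(n), cprime = rnorm(n), ab = a * b)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Random trial dataset for one subject with shared covariates.
random_trial_data <- function(n_trials = 40) {
  tibble::tibble(
    subject = 1L,
    x = sample(c(-1, 1), n_trials, replace = TRUE),
    m = rnorm(n_trials),
    rating = rnorm(n_trials),
    wine = sample(1:3, n_trials, replace = TRUE),
    payment = sample(0:1, n_trials, replace = TRUE)
  )
}
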