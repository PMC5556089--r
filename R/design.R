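#' Specification of the within-subject tasting design
#'
#' Describes the factorial wine-tasting design: 3 price levels crossed with
#' 2 payment conditions, each cell repeated 18 times and the 108 trials
#' split over 3 scanner runs of 36 trials. Three wines rotate through all
#' conditions equally often. Pseudo-randomization constraints (enforced by
#' [generate_design()]): the same wine never appears on successive trials,
#' and price and payment levels repeat at most twice in a row.
#'
#' @param n_price_levels Number of price-cue levels (default 3).
#' @param n_payment_levels Number of payment conditions (default 2; 0 =
#'   taste for free, 1 = pay).
#' @param reps_per_condition Repetitions of each price x payment cell
#'   (default 18).
#' @param n_runs Number of scanner runs (default 3).
#' @param n_wines Number of wines rotated through the conditions (default 3).
#' @param tasting_duration_s Modelled tasting epoch in seconds (default 3;
#'   the swirl period itself lasts 8 s, see `details`).
#' @param tr_s Repetition time of the scanner, seconds (default 2.5).
#' @param isi_bounds_s Jitter bounds (seconds) of the two intervals inside a
#'   trial (cue-to-taste and taste-to-rating), default `c(6, 8)`.
#' @param iti_bounds_s Jitter bounds (seconds) of the inter-trial interval,
#'   default `c(7, 9)`.
#'
#' @details Trial timing mirrors the scanning protocol: a 2.5-s price and
#'   payment cue, a jittered 6-8-s fixation, wine delivery with an 8-s
#'   swirl (of which the first `tasting_duration_s` seconds are modelled),
#'   a 2-s swallow cue, a jittered 6-8-s fixation, an 8-s pleasantness
#'   rating, a 3-s rinse, a 2-s swallow and a jittered 7-9-s inter-trial
#'   fixation.
#'
#' @return An object of class `design_spec`.
#' @seealso [generate_design()]
#' @export
design_spec <- function(n_price_levels = 3, n_payment_levels = 2,
                        reps_per_condition = 18, n_runs = 3, n_wines = 3,
                        tasting_duration_s = 3, tr_s = 2.5,
                        isi_bounds_s = c(6, 8), iti_bounds_s = c(7, 9)) {
  for (nm in c("n_price_levels", "n_payment_levels", "reps_per_condition",
               "n_runs", "n_wines")) {
    if (!is_count(get(nm)) || get(nm) < 1)
      abort(sprintf("`%s` must be a positive integer.", nm))
  }
  stopifnot_scalar_number(tasting_duration_s, "tasting_duration_s", lower = 0)
  stopifnot_scalar_number(tr_s, "tr_s", lower = 0.1)
  n_trials <- n_price_levels * n_payment_levels * reps_per_condition
  if (n_trials %% n_runs != 0) {
    abort("total trial count must divide evenly into `n_runs`.")
  }
  if (reps_per_condition %% (n_wines * n_runs) != 0) {
    abort(paste0("`reps_per_condition` must be a multiple of `n_wines * n_runs` ",
                 "so every wine appears equally often in every condition and run."))
  }
  structure(
    list(n_price_levels = n_price_levels,
         n_payment_levels = n_payment_levels,
         reps_per_condition = reps_per_condition,
         n_runs = n_runs,
         trials_per_run = n_trials %/% n_runs,
         n_trials = n_trials,
         n_wines = n_wines,
         tasting_duration_s = tasting_duration_s,
         tr_s = tr_s,
         isi_bounds_s = isi_bounds_s,
         iti_bounds_s = iti_bounds_s),
    class = "design_spec"
  )
}

#' Generate a pseudo-randomized trial table
#'
#' Draws one realization of the tasting design under the pseudo-randomization
#' constraints: the same wine never on two successive trials, and no more
#' than two successive trials sharing a price level or a payment condition
#' (constraints apply within each run). Condition sequences are sampled by a
#' constrained sequential sampler that restarts a run when it paints itself
#' into a corner, so the output is exactly balanced: every
#' price x payment x wine combination appears equally often in every run.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed; the seed fully determines the output.
#' @return A tibble with one row per trial: `trial`, `run`, `price` (level
#'   `1..n_price_levels`, 1 = cheapest), `payment` (0 free / 1 pay), `wine`,
#'   `onset_s` (tasting onset in seconds from run start), `rating` (`NA`
#'   until simulated or measured) and `included` (all `TRUE`; flipped by QC).
#' @examples
#' d <- generate_design(seed = 1)
#' nrow(d)             # 108
#' table(d$price, d$payment)
#' @export
generate_design <- function(spec = design_spec(), seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$n_wines < 2) {
    abort(paste("infeasible design: with fewer than 2 wines the constraint",
                "'no two successive trials share the same wine' cannot hold."))
  }
  if (spec$n_price_levels < 2 && spec$trials_per_run > 2) {
    abort(paste("infeasible design: with one price level the constraint",
                "'no more than two successive trials share the same price",
                "level' cannot hold."))
  }
  if (spec$n_payment_levels < 2 && spec$trials_per_run > 2) {
    abort(paste("infeasible design: with one payment condition the constraint",
                "'no more than two successive trials share the same payment",
                "condition' cannot hold."))
  }
  with_seed_(seed, {
    runs <- lapply(seq_len(spec$n_runs), function(r) {
      seq_tbl <- sample_run_sequence(spec)
      seq_tbl$run <- r
      seq_tbl
    })
    out <- dplyr::bind_rows(runs)
    out$trial <- seq_len(nrow(out))
    out$onset_s <- sample_onsets(spec)
    out$rating <- NA_real_
    out$included <- TRUE
    out[, c("trial", "run", "price", "payment", "wine", "onset_s",
            "rating", "included")]
  })
}

# Constrained sequential sampler for one run's condition sequence.
sample_run_sequence <- function(spec, max_restarts = 1000L) {
  cells <- expand.grid(price = seq_len(spec$n_price_levels),
                       payment = seq_len(spec$n_payment_levels) - 1L,
                       wine = seq_len(spec$n_wines))
  per_cell <- spec$trials_per_run / nrow(cells)
  n <- spec$trials_per_run
  for (attempt in seq_len(max_restarts)) {
    counts <- rep(per_cell, nrow(cells))
    price <- integer(n); payment <- integer(n); wine <- integer(n)
    ok <- TRUE
    for (t in seq_len(n)) {
      allowed <- counts > 0
      if (t >= 2) allowed <- allowed & cells$wine != wine[t - 1]
      if (t >= 3) {
        if (price[t - 1] == price[t - 2])
          allowed <- allowed & cells$price != price[t - 1]
        if (payment[t - 1] == payment[t - 2])
          allowed <- allowed & cells$payment != payment[t - 1]
      }
      idx <- which(allowed)
      if (length(idx) == 0L) { ok <- FALSE; break }
      pick <- if (length(idx) == 1L) idx else
        sample(idx, 1L, prob = counts[idx])
      price[t] <- cells$price[pick]
      payment[t] <- cells$payment[pick]
      wine[t] <- cells$wine[pick]
      counts[pick] <- counts[pick] - 1L
    }
    if (ok) {
      return(tibble(price = price, payment = payment, wine = wine))
    }
  }
  abort(paste("could not satisfy the pseudo-randomization constraints",
              "(no adjacent same wine; price/payment repeats capped at two)",
              "after", max_restarts, "restarts; the design may be infeasible."))
}

# Tasting onsets from the per-trial event sequence with jittered intervals.
sample_onsets <- function(spec) {
  n <- spec$trials_per_run
  onsets <- numeric(spec$n_runs * n)
  k <- 0L
  for (r in seq_len(spec$n_runs)) {
    t <- 0
    for (i in seq_len(n)) {
      t <- t + 2.5                                   # price/payment cue
      t <- t + runif(1, spec$isi_bounds_s[1], spec$isi_bounds_s[2])
      k <- k + 1L
      onsets[k] <- t                                 # tasting onset
      t <- t + 8 + 2                                 # swirl + swallow cue
      t <- t + runif(1, spec$isi_bounds_s[1], spec$isi_bounds_s[2])
      t <- t + 8 + 3 + 2                             # rating + rinse + swallow
      t <- t + runif(1, spec$iti_bounds_s[1], spec$iti_bounds_s[2])
    }
  }
  onsets
}

#' Check a trial table against the design constraints
#'
#' @param trials A trial table as returned by [generate_design()].
#' @param spec The [design_spec()] it should satisfy.
#' @return Invisibly `TRUE` if all constraints hold, otherwise a character
#'   vector naming each violated constraint.
#' @export
validate_design <- function(trials, spec = design_spec()) {
  bad <- character(0)
  if (nrow(trials) != spec$n_trials)
    bad <- c(bad, sprintf("expected %d trials, found %d", spec$n_trials, nrow(trials)))
  per_run <- table(trials$run)
  if (any(per_run != spec$trials_per_run))
    bad <- c(bad, "unequal trials per run")
  cell <- table(trials$price, trials$payment)
  if (any(cell != spec$reps_per_condition))
    bad <- c(bad, "price x payment cells not balanced")
  wine_cell <- table(trials$price, trials$payment, trials$wine)
  if (any(wine_cell != spec$reps_per_condition / spec$n_wines))
    bad <- c(bad, "wines not balanced across conditions")
  by_run <- split(trials, trials$run)
  for (tr in by_run) {
    if (any(tr$wine[-1] == tr$wine[-nrow(tr)]))
      bad <- c(bad, "same wine on successive trials")
    if (max_run_length(tr$price) > 2)
      bad <- c(bad, "more than two successive trials share a price level")
    if (max_run_length(tr$payment) > 2)
      bad <- c(bad, "more than two successive trials share a payment condition")
    if (any(diff(tr$onset_s) <= 0))
      bad <- c(bad, "onsets not strictly increasing within a run")
  }
  if (length(bad) == 0) invisible(TRUE) else unique(bad)
}

max_run_length <- function(x) {
  if (length(x) == 0) return(0L)
  max(rle(x)$lengths)
}
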