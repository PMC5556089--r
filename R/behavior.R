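#' Z-score a variable within subject
#'
#' Standardizes trial-level values to mean 0 and s.d. 1 separately for each
#' subject, using the sample (n - 1) standard deviation.
#'
#' @param values Numeric vector, one value per trial.
#' @param subject Subject identifier, same length as `values`.
#' @param name Variable name used in error messages.
#' @return Numeric vector of standardized values.
#' @examples
#' zscore_within_subject(c(1, 2, 3), c(1, 1, 1))  # -1, 0, 1
#' @export
zscore_within_subject <- function(values, subject, name = "values") {
  stopifnot(length(values) == length(subject))
  out <- numeric(length(values))
  for (s in unique(subject)) {
    sel <- subject == s
    sdv <- stats::sd(values[sel])
    if (!is.finite(sdv) || sdv == 0) {
      abort(sprintf("`%s` is constant within subject %s; cannot z-score.",
                    name, s))
    }
    out[sel] <- (values[sel] - mean(values[sel])) / sdv
  }
  out
}

#' Random-intercept mixed model for pleasantness ratings
#'
#' Fits, by maximum likelihood, the linear mixed-effects model for
#' experienced pleasantness with fixed effects for trial number (tasting
#' count per wine), wine, price cue and payment condition, all their
#' two-way interactions, the trial x price x payment three-way interaction
#' (12 fixed terms in all), and a random intercept per subject. All
#' regressors are z-scored across trials within each subject before
#' fitting; wine and price enter as numeric codes. Degrees of freedom use
#' the residual convention `df = n_obs - p`.
#'
#' @param data Trial-level tibble with columns `subject`, `rating`, `wine`,
#'   `price`, `payment`, and optionally `trial_no` (tasting count for that
#'   wine, 1..n). When `trial_no` is absent it is derived as the running
#'   count of tastings of each wine within subject, in `trial` order.
#' @param ci_level Confidence level for the fixed-effect intervals.
#' @return An object of class `rating_lmm`: list with `fixed` (tibble:
#'   `term`, `estimate`, `se`, `t`, `df`, `p`, `ci_lower`, `ci_upper`),
#'   `ranef_sd`, `sigma`, `n_obs`, `df`, `logLik`, `deviance`, `AIC`,
#'   `BIC`, and `model` (the underlying `lmerMod`).
#' @export
fit_rating_lmm <- function(data, ci_level = 0.95) {
  need <- c("subject", "rating", "wine", "price", "payment")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(sprintf("missing column(s): %s.", paste(miss, collapse = ", ")))
  data <- data[is.finite(data$rating), , drop = FALSE]
  if (length(unique(data$subject)) < 2) abort("need at least 2 subjects.")
  if (!"trial_no" %in% names(data)) {
    ord <- if ("trial" %in% names(data)) order(data$subject, data$trial)
    else seq_len(nrow(data))
    data <- data[ord, , drop = FALSE]
    data <- dplyr::mutate(dplyr::group_by(data, .data$subject, .data$wine),
                          trial_no = dplyr::row_number())
    data <- dplyr::ungroup(data)
  }
  df_fit <- tibble(
    subject = data$subject,
    rating = data$rating,
    ztrial = zscore_within_subject(data$trial_no, data$subject, "trial_no"),
    zwine = zscore_within_subject(data$wine, data$subject, "wine"),
    zprice = zscore_within_subject(data$price, data$subject, "price"),
    zpay = zscore_within_subject(data$payment, data$subject, "payment")
  )
  form <- rating ~ (ztrial + zwine + zprice + zpay)^2 +
    ztrial:zprice:zpay + (1 | subject)
  fit <- lme4::lmer(form, data = df_fit, REML = FALSE)
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$messages) && any(grepl("failed to converge", conv$messages))) {
    abort(paste("mixed model failed to converge:",
                paste(conv$messages, collapse = "; ")))
  }
  sm <- summary(fit)$coefficients
  n_obs <- nrow(df_fit)
  p <- nrow(sm)
  dfree <- n_obs - p
  tcrit <- qt(1 - (1 - ci_level) / 2, dfree)
  fixed <- tibble(
    term = pretty_lmm_terms(rownames(sm)),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    t = sm[, "t value"],
    df = dfree,
    p = 2 * pt(-abs(sm[, "t value"]), dfree),
    ci_lower = sm[, "Estimate"] - tcrit * sm[, "Std. Error"],
    ci_upper = sm[, "Estimate"] + tcrit * sm[, "Std. Error"]
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  ll <- as.numeric(stats::logLik(fit))
  structure(
    list(fixed = fixed,
         ranef_sd = vc$sdcor[vc$grp == "subject"],
         sigma = stats::sigma(fit),
         n_obs = n_obs, n_fixed = p, df = dfree,
         logLik = ll, deviance = -2 * ll,
         AIC = stats::AIC(fit), BIC = stats::BIC(fit),
         model = fit),
    class = "rating_lmm"
  )
}

pretty_lmm_terms <- function(x) {
  map <- c("(Intercept)" = "Intercept", ztrial = "Trial number",
           zwine = "Wine", zprice = "Price cue", zpay = "Payment")
  vapply(strsplit(x, ":", fixed = TRUE), function(parts) {
    paste(ifelse(parts %in% names(map), map[parts], parts), collapse = " by ")
  }, character(1))
}

#' Paired contrast of per-subject means
#'
#' Standard paired two-tailed t-test on per-subject differences, used for
#' the informed-versus-blind tasting comparison. Zero-variance differences
#' are flagged degenerate rather than erroring.
#'
#' @param informed,blind Equal-length numeric vectors of per-subject means.
#' @param ci_level Confidence level.
#' @return A one-row tibble: `mean_diff`, `se`, `t`, `df`, `p`, `ci_lower`,
#'   `ci_upper`, `degenerate`.
#' @export
paired_contrast <- function(informed, blind, ci_level = 0.95) {
  if (length(informed) != length(blind)) abort("inputs must have equal length.")
  n <- length(informed)
  if (n < 2) abort("need at least 2 pairs.")
  d <- informed - blind
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(tibble(mean_diff = md, se = 0,
                  t = if (md == 0) 0 else sign(md) * Inf,
                  df = n - 1, p = if (md == 0) 1 else 0,
                  ci_lower = md, ci_upper = md, degenerate = TRUE))
  }
  tt <- stats::t.test(informed, blind, paired = TRUE, conf.level = ci_level)
  tibble(mean_diff = unname(tt$estimate), se = unname(tt$stderr),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
         degenerate = FALSE)
}
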