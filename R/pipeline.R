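#' Evaluate the SPAM against a pooled correlation set
#'
#' The six-step evaluation procedure for a two-construct, two-occasion
#' correlation structure:
#' simulate a large dataset carrying the input correlations (step 2), fit
#' the SPAM to it (step 3), simulate a new dataset carrying the SPAM's
#' predicted correlations (step 4), compute the four standardized effects in
#' both directions on the new dataset (step 5), and compare the adjusted
#' lagged effects predicted by the SPAM with those implied by the input
#' correlations (step 6). Sign patterns of both effect sets are classified
#' against the true-vs-spurious templates.
#'
#' @param cs Complete, positive-definite [correlation_set()].
#' @param n Simulation size for steps 2 and 4 (default 10,000).
#' @param s Association sign of the construct pair.
#' @param seed Integer seed for the simulations.
#' @param exact If `TRUE` (default) the simulated datasets carry the target
#'   correlations exactly, making the whole report deterministic given the
#'   inputs.
#' @param epsilon Zero-band for [classify_signs()].
#' @return An object of class `spam_evaluation`: the input set and its
#'   effects, the `spam_fit`, the SPAM-predicted correlation set and its
#'   (simulated) effects, per-effect deltas, verdicts for both effect sets,
#'   and provenance (`n`, `seed`, `exact`, package version).
#' @examples
#' lon_sa <- correlation_set(0.603, 0.493, 0.379, 0.351, 0.552, 0.568)
#' ev <- spam_evaluation(lon_sa, n = 1000, s = 1, seed = 1)
#' tidy(ev)
#' @export
spam_evaluation <- function(cs, n = 10000, s = 1, seed = 1, exact = TRUE,
                            epsilon = 0.02) {
  cs <- as_correlation_set(cs)
  require_entries(cs, COR_NAMES)
  if (n < 100) abort("`n` must be at least 100.", class = "prospam_error_validation")

  ## step 2: large dataset with the input correlations
  dat <- simulate_two_wave(cs, n = n, seed = seed, exact = exact)
  sample_cs <- sample_correlations(dat)
  ## step 3: fit the SPAM
  fit <- fit_spam(sample_cs, n_obs = n, s = s)
  predicted <- fit$implied
  ## step 4: new dataset with the predicted correlations
  dat2 <- simulate_two_wave(predicted, n = n, seed = seed + 1L, exact = exact)
  ## step 5: effects in the new dataset
  predicted_effects <- empirical_effects(dat2)
  ## step 6: compare with the input-derived effects
  input_effects <- effects_bundle(cs)
  eff_cols <- c("beta_lag_fwd", "beta_lag_rev", "beta_change", "beta_change_on_change")
  deltas <- predicted_effects
  deltas[eff_cols] <- predicted_effects[eff_cols] - input_effects[eff_cols]

  out <- list(
    input = cs,
    input_effects = input_effects,
    fit = fit,
    predicted = predicted,
    predicted_effects = predicted_effects,
    deltas = deltas,
    input_verdicts = classify_signs(input_effects, epsilon = epsilon),
    predicted_verdicts = classify_signs(predicted_effects, epsilon = epsilon),
    provenance = list(n = n, s = s, seed = seed, exact = exact, epsilon = epsilon,
                      package_version = as.character(utils::packageVersion("prospam")))
  )
  class(out) <- "spam_evaluation"
  out
}

#' @export
print.spam_evaluation <- function(x, ...) {
  cat("SPAM evaluation (n =", x$provenance$n, ", exact =", x$provenance$exact, ")\n\n")
  print(x$fit)
  cat("\nSPAM-predicted effects:\n")
  print(as.data.frame(x$predicted_effects), digits = 3)
  cat("\nVerdicts:", paste(x$predicted_verdicts$direction, "=",
                           x$predicted_verdicts$verdict, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname spam_evaluation
#' @param x A `spam_evaluation` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.spam_evaluation <- function(x, ...) {
  eff_cols <- c("beta_lag_fwd", "beta_lag_rev", "beta_change", "beta_change_on_change")
  long <- function(df, which) {
    tidyr::pivot_longer(df[c("direction", eff_cols)], cols = dplyr::all_of(eff_cols),
                        names_to = "effect", values_to = which)
  }
  dplyr::left_join(long(x$input_effects, "input"),
                   long(x$predicted_effects, "predicted"),
                   by = c("direction", "effect")) |>
    dplyr::mutate(delta = .data$predicted - .data$input)
}

#' @rdname spam_evaluation
#' @exportS3Method generics::glance
glance.spam_evaluation <- function(x, ...) {
  dplyr::mutate(glance(x$fit),
                verdict_xy = x$predicted_verdicts$verdict[x$predicted_verdicts$direction == "xy"],
                verdict_yx = x$predicted_verdicts$verdict[x$predicted_verdicts$direction == "yx"])
}

#' Full SPAM analysis of a raw two-wave dataset
#'
#' For user-supplied data with columns `X1, X2, Y1, Y2`: computes the sample
#' correlations, the four standardized effects per direction with
#' conventional least-squares 95% confidence intervals, fits the SPAM
#' directly to the sample matrix, and classifies the sign patterns (using
#' the CI-contains-zero rule for the zero band).
#'
#' @param data Data frame with the four columns and at least 30 rows.
#' @param s Association sign of the construct pair.
#' @param epsilon Fallback zero-band where a standard error is unavailable.
#' @return An object of class `two_wave_analysis`: sample correlation set,
#'   effects with standard errors and CIs, the `spam_fit`, and verdicts.
#' @export
analyze_two_wave <- function(data, s = 1, epsilon = 0.02) {
  data <- as_two_wave(data)
  if (nrow(data) < 30) abort("Need at least 30 rows.", class = "prospam_error_validation")
  cs <- sample_correlations(data)
  eff <- empirical_effects(data)
  se <- effect_standard_errors(data)
  fit <- fit_spam(cs, n_obs = nrow(data), s = s)
  eff_cols <- c("beta_lag_fwd", "beta_lag_rev", "beta_change", "beta_change_on_change")
  ci_low <- eff; ci_high <- eff
  ci_low[eff_cols] <- eff[eff_cols] - qnorm(0.975) * se[eff_cols]
  ci_high[eff_cols] <- eff[eff_cols] + qnorm(0.975) * se[eff_cols]
  out <- list(
    sample = cs, effects = eff, se = se, ci_low = ci_low, ci_high = ci_high,
    fit = fit,
    verdicts = classify_signs(eff, epsilon = epsilon, se = se),
    n = nrow(data), s = s
  )
  class(out) <- "two_wave_analysis"
  out
}

effect_standard_errors <- function(data) {
  z <- lapply(as_two_wave(data), function(v) (v - mean(v)) / sd(v))
  se_of <- function(y, x, covariate = NULL) {
    fit <- if (is.null(covariate)) lm(y ~ x) else lm(y ~ x + covariate)
    ## SE of the standardized coefficient via the sd ratio
    unname(sqrt(diag(stats::vcov(fit)))[2] * sd(x) / sd(y))
  }
  dX <- z$X2 - z$X1; dY <- z$Y2 - z$Y1
  coc_se <- se_of(dY, dX)
  out <- dplyr::bind_rows(
    tibble::tibble(direction = "xy",
                   beta_lag_fwd = se_of(z$Y2, z$X1, z$Y1),
                   beta_lag_rev = se_of(z$Y1, z$X1, z$Y2),
                   beta_change = se_of(dY, z$X1),
                   beta_change_on_change = coc_se),
    tibble::tibble(direction = "yx",
                   beta_lag_fwd = se_of(z$X2, z$Y1, z$X1),
                   beta_lag_rev = se_of(z$X1, z$Y1, z$X2),
                   beta_change = se_of(dX, z$Y1),
                   beta_change_on_change = coc_se)
  )
  out
}

#' @export
print.two_wave_analysis <- function(x, ...) {
  cat("Two-wave SPAM analysis (n =", x$n, ")\n\n")
  print(x$fit)
  cat("\nEmpirical effects (with 95% CI):\n")
  eff_cols <- c("beta_lag_fwd", "beta_lag_rev", "beta_change", "beta_change_on_change")
  for (i in seq_len(nrow(x$effects))) {
    cat(" ", x$effects$direction[i], ":",
        paste(sprintf("%s = %.3f [%.3f; %.3f]", eff_cols,
                      unlist(x$effects[i, eff_cols]),
                      unlist(x$ci_low[i, eff_cols]),
                      unlist(x$ci_high[i, eff_cols])), collapse = "  "), "\n")
  }
  cat("\nVerdicts:", paste(x$verdicts$direction, "=", x$verdicts$verdict, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname analyze_two_wave
#' @param x A `two_wave_analysis` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.two_wave_analysis <- function(x, ...) {
  eff_cols <- c("beta_lag_fwd", "beta_lag_rev", "beta_change", "beta_change_on_change")
  long <- function(df, which) {
    tidyr::pivot_longer(df[c("direction", eff_cols)], cols = dplyr::all_of(eff_cols),
                        names_to = "effect", values_to = which)
  }
  long(x$effects, "estimate") |>
    dplyr::left_join(long(x$se, "std.error"), by = c("direction", "effect")) |>
    dplyr::left_join(long(x$ci_low, "conf.low"), by = c("direction", "effect")) |>
    dplyr::left_join(long(x$ci_high, "conf.high"), by = c("direction", "effect"))
}

#' @rdname analyze_two_wave
#' @exportS3Method generics::glance
glance.two_wave_analysis <- function(x, ...) {
  dplyr::mutate(glance(x$fit),
                verdict_xy = x$verdicts$verdict[x$verdicts$direction == "xy"],
                verdict_yx = x$verdicts$verdict[x$verdicts$direction == "yx"])
}
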