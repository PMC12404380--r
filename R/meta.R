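#' Fisher z transformation
#'
#' Variance-stabilizing transform for correlations (and, by the convention
#' adopted here, standardized regression effects): `z = atanh(r)`, with
#' sampling variance `1/(n - 3)`.
#'
#' @param r Correlation(s), strictly inside (-1, 1).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.na(r) & abs(r) >= 1)) {
    abort("Fisher z requires |r| < 1.", class = "prospam_error_validation")
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher-z value(s).
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Per-study effects from a study record
#'
#' Applies the closed-form effect calculus to each study's correlations.
#' Studies lacking some correlations (e.g. no time-2 outcome measure) yield
#' `NA` for the effects that need them, so downstream pooling aggregates
#' over fewer studies for those rows.
#'
#' @param studies Data frame with columns `study`, `n` and the six `r_*`
#'   correlation columns (blank = missing), as produced by
#'   [make_study_fixtures()] or [read_study_table()].
#' @return A long tibble: `study`, `n`, `direction`, `effect`, `estimate`.
#' @export
study_effects <- function(studies) {
  purrr::map_dfr(seq_len(nrow(studies)), function(i) {
    row <- studies[i, ]
    cs <- as_correlation_set(row[intersect(names(row), COR_NAMES)])
    eb <- effects_bundle(cs)
    tidyr::pivot_longer(eb, cols = dplyr::starts_with("beta_"),
                        names_to = "effect", values_to = "estimate") |>
      dplyr::mutate(study = row$study, n = row$n, .before = 1)
  })
}

#' Random-effects pooling of Fisher-z values
#'
#' Pools per-study Fisher-z estimates under a random-effects model:
#' between-study variance by REML (default) or DerSimonian-Laird, weights
#' `1/(v_i + tau2)`, a normal-theory 95% CI, Cochran's Q on fixed-effect
#' weights, and the Q-based Higgins `I2 = max(0, (Q - df)/Q) * 100` with a
#' Q-profile confidence interval. Pooled values and CI bounds are
#' back-transformed to the correlation scale.
#'
#' @param z Per-study estimates on the Fisher-z scale.
#' @param vi Their sampling variances (e.g. `1/(n - 3)`).
#' @param method `"REML"` (default) or `"DL"`.
#' @return One-row tibble: `k`, `pooled`, `ci_low`, `ci_high` (r scale),
#'   `pooled_z`, `se_z`, `tau2`, `q`, `q_df`, `q_p`, `i2`, `i2_low`,
#'   `i2_high`. With `k = 1` the study passes through and heterogeneity
#'   statistics are `NA`.
#' @export
meta_pool <- function(z, vi, method = c("REML", "DL")) {
  method <- match.arg(method)
  keep <- !is.na(z) & !is.na(vi)
  z <- z[keep]; vi <- vi[keep]
  if (!length(z)) abort("No estimates to pool.", class = "prospam_error_validation")
  if (any(vi <= 0)) abort("Sampling variances must be positive.", class = "prospam_error_validation")
  k <- length(z)
  if (k == 1L) {
    ci <- z + c(-1, 1) * qnorm(0.975) * sqrt(vi)
    return(tibble::tibble(k = 1L, pooled = tanh(z), ci_low = tanh(ci[1]), ci_high = tanh(ci[2]),
                          pooled_z = z, se_z = sqrt(vi), tau2 = NA_real_,
                          q = NA_real_, q_df = 0L, q_p = NA_real_,
                          i2 = NA_real_, i2_low = NA_real_, i2_high = NA_real_))
  }
  fit <- metafor::rma.uni(yi = z, vi = vi, method = method, test = "z")
  q_df <- k - 1L
  i2 <- max(0, (fit$QE - q_df) / fit$QE) * 100
  i2_ci <- tryCatch({
    ci <- suppressWarnings(stats::confint(fit))
    c(ci$random["I^2(%)", "ci.lb"], ci$random["I^2(%)", "ci.ub"])
  }, error = function(e) c(NA_real_, NA_real_))
  tibble::tibble(
    k = k,
    pooled = tanh(as.numeric(fit$beta)),
    ci_low = tanh(fit$ci.lb), ci_high = tanh(fit$ci.ub),
    pooled_z = as.numeric(fit$beta), se_z = fit$se,
    tau2 = fit$tau2, q = fit$QE, q_df = q_df, q_p = fit$QEp,
    i2 = i2, i2_low = i2_ci[1], i2_high = i2_ci[2]
  )
}

META_ROWS <- tibble::tibble(
  association = c(COR_NAMES,
                  paste0(c("beta_lag_fwd", "beta_lag_rev", "beta_change", "beta_change_on_change"), "_xy"),
                  paste0(c("beta_lag_fwd", "beta_lag_rev", "beta_change", "beta_change_on_change"), "_yx")),
  kind = c(rep("correlation", 6), rep("effect", 8))
)

#' Meta-analytic table of correlations and effects across studies
#'
#' Runs the 14 random-effects meta-analyses of a two-wave multi-study
#' synthesis: one per zero-order correlation (6) and one per standardized
#' effect and direction (8; the change-on-change rows are identical across
#' directions by construction). All pooling happens on the Fisher-z scale
#' with sampling variances `1/(n - 3)` and results are back-transformed.
#'
#' @param studies Per-study table as for [study_effects()].
#' @param method Between-study variance estimator, `"REML"` or `"DL"`.
#' @return A 14-row tibble of class `spam_meta`: `association`, `kind`, `k`,
#'   `n_total`, and the [meta_pool()] columns.
#' @export
meta_table <- function(studies, method = "REML") {
  if (nrow(studies) < 2) abort("Need at least 2 studies.", class = "prospam_error_validation")
  eff <- study_effects(studies)
  pool_rows <- purrr::map_dfr(seq_len(nrow(META_ROWS)), function(i) {
    assoc <- META_ROWS$association[i]
    if (META_ROWS$kind[i] == "correlation") {
      est <- studies[[assoc]]
      n <- studies$n
    } else {
      effect_name <- sub("_(xy|yx)$", "", assoc)
      dir <- sub("^.*_(xy|yx)$", "\\1", assoc)
      sel <- eff$effect == effect_name & eff$direction == dir
      est <- eff$estimate[sel]
      n <- eff$n[sel]
    }
    keep <- !is.na(est) & !is.na(n) & n > 3
    res <- meta_pool(fisher_z(est[keep]), 1 / (n[keep] - 3), method = method)
    dplyr::mutate(res, association = assoc, kind = META_ROWS$kind[i],
                  n_total = sum(n[keep]), .before = 1)
  })
  class(pool_rows) <- c("spam_meta", class(pool_rows))
  pool_rows
}
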