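#' Standardized partial regression coefficient from three correlations
#'
#' The expected standardized coefficient of a predictor `x` on an outcome `y`
#' adjusting for a single covariate `z` is a pure function of the three
#' pairwise correlations:
#' \deqn{\beta_{x,y.z} = \frac{r_{xy} - r_{xz} r_{yz}}{1 - r_{xz}^2}}
#' This is the building block of the adjusted (cross-lagged) prospective
#' effects: with `x = X1`, `y = Y2`, `z = Y1` it gives the classic effect of
#' X at time 1 on Y at time 2 adjusting for Y at time 1.
#'
#' @param r_xy Correlation between predictor and outcome.
#' @param r_xz Correlation between predictor and covariate.
#' @param r_yz Correlation between outcome and covariate.
#' @return The standardized partial coefficient (scalar).
#' @examples
#' partial_beta(0.379, 0.493, 0.568) # 0.1308
#' @export
partial_beta <- function(r_xy, r_xz, r_yz) {
  validate_correlations(c(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz))
  if (is.na(r_xy) || is.na(r_xz) || is.na(r_yz)) return(NA_real_)
  (r_xy - r_xz * r_yz) / (1 - r_xz^2)
}

direction_roles <- function(direction) {
  ## map the generic (predictor construct, outcome construct) roles onto
  ## correlation-set columns; "yx" swaps X and Y
  if (direction == "xy") {
    list(auto_out = "r_y1y2", auto_pred = "r_x1x2",
         conc1 = "r_x1y1", conc2 = "r_x2y2",
         cross_fwd = "r_x1y2",  # pred t1 with outcome t2
         cross_rev = "r_x2y1")  # pred t2 with outcome t1
  } else {
    list(auto_out = "r_x1x2", auto_pred = "r_y1y2",
         conc1 = "r_x1y1", conc2 = "r_x2y2",
         cross_fwd = "r_x2y1",  # Y1 with X2
         cross_rev = "r_x1y2")  # Y2 with X1
  }
}

#' Adjusted lagged (cross-lagged) effects
#'
#' Computes the two adjusted prospective effects for one direction: the
#' forward effect of the predictor at time 1 on the outcome at time 2
#' adjusting for the outcome at time 1, and the time-reversed effect of the
#' predictor at time 1 on the outcome at time 1 adjusting for the outcome at
#' time 2. Under a true increasing (decreasing) effect these two should have
#' opposite signs; under a spurious association driven by regression to the
#' mean they share a sign.
#'
#' @param cs A [correlation_set()].
#' @param direction `"xy"` (X predicts Y) or `"yx"`.
#' @return Named numeric vector `c(beta_lag_fwd, beta_lag_rev)`.
#' @export
lagged_effects <- function(cs, direction = c("xy", "yx")) {
  direction <- match.arg(direction)
  cs <- as_correlation_set(cs)
  r <- direction_roles(direction)
  require_entries(cs, c(r$conc1, r$cross_fwd, r$auto_out))
  c(beta_lag_fwd = partial_beta(cs[[r$cross_fwd]], cs[[r$conc1]], cs[[r$auto_out]]),
    beta_lag_rev = partial_beta(cs[[r$conc1]], cs[[r$cross_fwd]], cs[[r$auto_out]]))
}

#' Effect of the time-1 predictor on the outcome change score
#'
#' The expected standardized crude effect of the predictor at time 1 on the
#' difference between the standardized outcome at time 2 and at time 1:
#' \deqn{\beta_{x_1, y_2 - y_1} = \frac{r_{x_1 y_2} - r_{x_1 y_1}}
#'   {\sqrt{2 (1 - r_{y_1 y_2})}}}
#' The denominator is the standard deviation of the difference of two
#' standardized variables, hence the square root.
#'
#' @inheritParams lagged_effects
#' @return The standardized change effect (scalar).
#' @export
change_effect <- function(cs, direction = c("xy", "yx")) {
  direction <- match.arg(direction)
  cs <- as_correlation_set(cs)
  r <- direction_roles(direction)
  require_entries(cs, c(r$cross_fwd, r$conc1, r$auto_out))
  if (cs[[r$auto_out]] >= 1 - 1e-12) {
    abort("Outcome autocorrelation of 1 gives a zero-variance difference score.",
          class = "prospam_error_degenerate")
  }
  (cs[[r$cross_fwd]] - cs[[r$conc1]]) / sqrt(2 * (1 - cs[[r$auto_out]]))
}

#' Effect of the predictor change score on the outcome change score
#'
#' The expected standardized effect of `X2 - X1` on `Y2 - Y1` (components
#' standardized before differencing):
#' \deqn{\beta_{\Delta x, \Delta y} = \frac{r_{x_1 y_1} + r_{x_2 y_2}
#'   - r_{x_1 y_2} - r_{x_2 y_1}}
#'   {\sqrt{4 (1 - r_{x_1 x_2})(1 - r_{y_1 y_2})}}}
#' It is symmetric under exchanging the X and Y roles, so it is identical in
#' both directions. Its sign is driven by the excess of the concurrent over
#' the cross-lagged correlations, i.e. by occasion-specific state influence.
#'
#' @param cs A [correlation_set()].
#' @return The standardized change-on-change effect (scalar).
#' @export
change_on_change_effect <- function(cs) {
  cs <- as_correlation_set(cs)
  require_entries(cs, COR_NAMES)
  if (cs$r_x1x2 >= 1 - 1e-12 || cs$r_y1y2 >= 1 - 1e-12) {
    abort("Autocorrelation of 1 gives a zero-variance difference score.",
          class = "prospam_error_degenerate")
  }
  (cs$r_x1y1 + cs$r_x2y2 - cs$r_x1y2 - cs$r_x2y1) /
    sqrt(4 * (1 - cs$r_x1x2) * (1 - cs$r_y1y2))
}

#' All four standardized effects in both directions
#'
#' Assembles, per direction, the forward and reverse adjusted lagged effects,
#' the change effect, and the change-on-change effect. Effects whose required
#' correlations are missing come back as `NA` instead of failing the whole
#' bundle, so incomplete study records still yield the subset they support.
#'
#' @param cs A [correlation_set()].
#' @return A tibble with two rows (`direction` = `"xy"`, `"yx"`) and columns
#'   `beta_lag_fwd`, `beta_lag_rev`, `beta_change`, `beta_change_on_change`.
#' @examples
#' lon_sa <- correlation_set(0.603, 0.493, 0.379, 0.351, 0.552, 0.568)
#' effects_bundle(lon_sa)
#' @export
effects_bundle <- function(cs) {
  cs <- as_correlation_set(cs)
  safe <- function(expr) tryCatch(expr, prospam_error_missing_input = function(e) NA_real_)
  coc <- safe(change_on_change_effect(cs))
  rows <- purrr::map(c("xy", "yx"), function(dir) {
    lag <- safe(lagged_effects(cs, dir))
    if (length(lag) == 1L && is.na(lag)) lag <- c(beta_lag_fwd = NA_real_, beta_lag_rev = NA_real_)
    tibble::tibble(
      direction = dir,
      beta_lag_fwd = lag[["beta_lag_fwd"]],
      beta_lag_rev = lag[["beta_lag_rev"]],
      beta_change = safe(change_effect(cs, dir)),
      beta_change_on_change = coc
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("effects_bundle", class(out))
  out
}

SIGN_TEMPLATES <- list(
  "true-increasing"   = list(lag_fwd = "+", lag_rev = "-", change = "+", coc = "+"),
  "true-decreasing"   = list(lag_fwd = "-", lag_rev = "+", change = "-", coc = "-"),
  "spurious-positive" = list(lag_fwd = "+", lag_rev = "+", change = c("0", "-"), coc = c("0", "+")),
  "spurious-negative" = list(lag_fwd = "-", lag_rev = "-", change = c("0", "+"), coc = c("0", "-"))
)

eps_sign <- function(x, epsilon) {
  dplyr::case_when(is.na(x) ~ NA_character_,
                   x > epsilon ~ "+", x < -epsilon ~ "-", TRUE ~ "0")
}

#' Classify the sign pattern of a four-effect bundle
#'
#' Maps the epsilon-banded signs of the four effects per direction onto the
#' diagnostic templates: a true increasing effect predicts `(+, -, +, +)`
#' (forward lagged, reverse lagged, change, change-on-change), a true
#' decreasing effect the mirror image, while spurious associations predict
#' both lagged effects sharing a sign with a zero-or-opposite change effect
#' and a zero-or-same-as-lagged change-on-change effect. Patterns matching no
#' template are `"inconclusive"`.
#'
#' @param bundle An [effects_bundle()] tibble (or a data frame with the same
#'   columns).
#' @param epsilon Non-negative half-width of the "zero" band on the
#'   standardized scale. Effects inside `[-epsilon, epsilon]` count as zero.
#'   The default 0.02 is small relative to conventionally interpretable
#'   standardized effects.
#' @param se Optional data frame with the same shape as `bundle` holding
#'   standard errors; when supplied, an effect counts as zero when its 95%
#'   confidence interval contains zero (the CI mode), instead of the
#'   epsilon band.
#' @return A tibble with one row per direction: the four signs, and
#'   `verdict` in `"true-increasing"`, `"true-decreasing"`,
#'   `"spurious-positive"`, `"spurious-negative"`, `"inconclusive"`.
#' @export
classify_signs <- function(bundle, epsilon = 0.02, se = NULL) {
  stopifnot(epsilon >= 0)
  eff_cols <- c("beta_lag_fwd", "beta_lag_rev", "beta_change", "beta_change_on_change")
  sgn <- function(col, i) {
    x <- bundle[[col]][i]
    if (!is.null(se)) {
      s <- se[[col]][i]
      if (!is.na(x) && !is.na(s) && abs(x) <= 1.959964 * s) return("0")
      return(eps_sign(x, 0))
    }
    eps_sign(x, epsilon)
  }
  purrr::map_dfr(seq_len(nrow(bundle)), function(i) {
    signs <- vapply(eff_cols, sgn, character(1), i = i)
    verdict <- "inconclusive"
    if (!anyNA(signs)) {
      for (nm in names(SIGN_TEMPLATES)) {
        tpl <- SIGN_TEMPLATES[[nm]]
        if (signs[1] %in% tpl$lag_fwd && signs[2] %in% tpl$lag_rev &&
            signs[3] %in% tpl$change && signs[4] %in% tpl$coc) {
          verdict <- nm
          break
        }
      }
      if (all(signs == "0")) verdict <- "inconclusive"
    }
    tibble::tibble(
      direction = if (is.null(bundle$direction)) NA_character_ else bundle$direction[i],
      sign_lag_fwd = signs[1], sign_lag_rev = signs[2],
      sign_change = signs[3], sign_change_on_change = signs[4],
      verdict = verdict, epsilon = epsilon
    )
  })
}
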