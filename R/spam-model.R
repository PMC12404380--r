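#' SPAM parameters
#'
#' The spurious prospective associations model (SPAM) generates two-wave data
#' on two constructs without any causal effect between them. An overarching
#' trait loads on the general level of each construct with equal magnitude
#' `a` (same sign for positively associated constructs, opposite signs for
#' negatively associated ones, encoded by `s`); the general levels load on
#' their occasion measurements with stabilities `b` (construct X) and `c`
#' (construct Y); and an occasion-specific state adds covariance `d` between
#' the standardized measurements taken at the same occasion. All observed
#' variances are fixed at 1, so residual variances are derived, not free.
#'
#' @param a Trait loading magnitude, in (0, 1). `a = 0` is tolerated for
#'   degenerate test cases.
#' @param s Association sign, `+1` or `-1`. The loadings on the two general
#'   levels are reported as `a1 = a` and `a2 = s * a`.
#' @param b Loading of general X on `X1` and `X2`, in (0, 1).
#' @param c Loading of general Y on `Y1` and `Y2`, in (0, 1).
#' @param d Occasion-specific state covariance between standardized `X_t` and
#'   `Y_t` (additive on the correlation scale); bounded by positive
#'   semidefiniteness of the implied matrix.
#' @return A one-row tibble of class `spam_params`.
#' @examples
#' spam_params(a = 0.790, s = 1, b = 0.777, c = 0.755, d = 0.158)
#' @export
spam_params <- function(a, s = 1, b, c, d = 0) {
  if (!s %in% c(-1, 1)) abort("`s` must be +1 or -1.", class = "prospam_error_validation")
  for (nm in c("a", "b", "c")) {
    v <- get(nm)
    lo <- if (nm == "a") 0 else 1e-12  # a = 0 boundary allowed for testing
    if (!is.finite(v) || v < lo || v >= 1) {
      abort(paste0("`", nm, "` must lie in (0, 1); got ", format(v), "."),
            class = "prospam_error_validation")
    }
  }
  if (!is.finite(d)) abort("`d` must be finite.", class = "prospam_error_validation")
  out <- tibble::tibble(a = unname(a), s = as.integer(s), b = unname(b),
                        c = unname(c), d = unname(d))
  class(out) <- c("spam_params", class(out))
  out
}

as_spam_params <- function(x) {
  if (inherits(x, "spam_params")) return(x)
  x <- as.list(x)
  spam_params(a = x$a, s = x$s %||% 1, b = x$b, c = x$c, d = x$d %||% 0)
}

## bare-matrix implied structure for optimizer hot paths (no tibbles)
implied_matrix <- function(a, s, b, c, d) {
  cross <- s * a^2 * b * c
  conc <- cross + d
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- b^2
  m[1, 3] <- m[3, 1] <- conc
  m[1, 4] <- m[4, 1] <- cross
  m[2, 3] <- m[3, 2] <- cross
  m[2, 4] <- m[4, 2] <- conc
  m[3, 4] <- m[4, 3] <- c^2
  m
}

#' Model-implied correlation structure of the SPAM
#'
#' With all variances standardized to 1, the SPAM implies
#' `r_x1x2 = b^2`, `r_y1y2 = c^2`, cross-lagged correlations
#' `s * a^2 * b * c` (equal in both lags), and concurrent correlations
#' `s * a^2 * b * c + d`. The model therefore predicts equal concurrent and
#' equal cross-lagged correlations, with `d` the concurrent excess.
#'
#' @param params A [spam_params()] object (or coercible list).
#' @param check_psd Error if the implied matrix is not positive
#'   semidefinite (the feasibility bound on `d`).
#' @return A [correlation_set()].
#' @export
implied_correlations <- function(params, check_psd = TRUE) {
  p <- as_spam_params(params)
  cross <- p$s * p$a^2 * p$b * p$c
  conc <- cross + p$d
  cs <- correlation_set(
    r_x1x2 = p$b^2, r_x1y1 = conc, r_x1y2 = cross,
    r_x2y1 = cross, r_x2y2 = conc, r_y1y2 = p$c^2
  )
  if (check_psd && !isTRUE(is_psd(cs))) {
    abort(paste0("Implied correlation matrix is not positive semidefinite; ",
                 "`d` = ", format(p$d), " is outside the feasible range for these loadings."),
          class = "prospam_error_invalid_params")
  }
  cs
}

#' Method-of-moments starting values for the SPAM
#'
#' Closed-form initializer used by [fit_spam()]: `b` and `c` from the square
#' roots of the autocorrelations, `a` from the mean absolute cross-lagged
#' correlation rescaled by `b * c` (clamped into \[0, 1\]), and `d` as the
#' mean concurrent minus the mean (signed) cross-lagged correlation. When the
#' two concurrent and the two cross-lagged correlations are internally equal
#' the model is just-identified in these moments and the initializer is
#' already the exact solution.
#'
#' @param cs A complete [correlation_set()].
#' @param s Association sign, `+1` or `-1`.
#' @return A [spam_params()] object.
#' @export
moment_start_values <- function(cs, s = 1) {
  cs <- as_correlation_set(cs)
  require_entries(cs, COR_NAMES)
  if (cs$r_x1x2 <= 0 || cs$r_y1y2 <= 0) {
    abort("Autocorrelations must be positive to initialize the SPAM.",
          class = "prospam_error_initialization")
  }
  b <- sqrt(cs$r_x1x2)
  c <- sqrt(cs$r_y1y2)
  cross <- mean(c(abs(cs$r_x1y2), abs(cs$r_x2y1)))
  a2 <- cross / (b * c)
  if (a2 > 1) {
    warn("Cross-lagged correlations exceed the loading bound; `a` clamped to 1 - 1e-6.")
    a2 <- 1 - 1e-6
  }
  a <- sqrt(a2)
  if (a == 0) warn("Mean cross-lagged correlation is zero; starting at the a = 0 boundary.")
  d <- mean(c(cs$r_x1y1, cs$r_x2y2)) - s * cross
  spam_params(a = a, s = s, b = b, c = c, d = d)
}

#' Simulate two-wave data from the SPAM
#'
#' Draws `n` multivariate-normal observations of `(X1, X2, Y1, Y2)` with mean
#' zero and the model-implied correlation structure. In exact mode the sample
#' correlation matrix equals the implied matrix to machine precision; in
#' stochastic mode it is an ordinary random draw.
#'
#' @param params A [spam_params()] object.
#' @param n Number of observations (at least 5).
#' @param seed Optional integer seed; the same seed reproduces the dataset.
#' @param exact If `TRUE` (default), impose the target correlations exactly.
#' @return A tibble with columns `X1`, `X2`, `Y1`, `Y2`.
#' @export
simulate_spam <- function(params, n, seed = NULL, exact = TRUE) {
  simulate_two_wave(implied_correlations(params), n = n, seed = seed, exact = exact)
}
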