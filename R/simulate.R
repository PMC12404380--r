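#' Simulate a two-wave dataset with a target correlation structure
#'
#' Multivariate-normal generation of `(X1, X2, Y1, Y2)` for an arbitrary
#' positive-definite target correlation set. Exact mode whitens a raw normal
#' draw and recolors it with the Cholesky factor of the target so that the
#' sample correlation matrix equals the target to machine precision (any
#' `n > 4` suffices); stochastic mode returns an ordinary seeded draw.
#'
#' @param cs Complete, positive-definite [correlation_set()] target.
#' @param n Number of rows (`> 4`).
#' @param seed Optional integer seed governing the draw.
#' @param exact If `TRUE` (default), impose the target correlations exactly.
#' @return A tibble with numeric columns `X1`, `X2`, `Y1`, `Y2`.
#' @examples
#' cs <- correlation_set(0.6, 0.5, 0.38, 0.35, 0.55, 0.57)
#' d <- simulate_two_wave(cs, n = 100, seed = 1)
#' max(abs(cor_set_matrix(sample_correlations(d)) - cor_set_matrix(cs)))
#' @export
simulate_two_wave <- function(cs, n, seed = NULL, exact = TRUE) {
  cs <- as_correlation_set(cs)
  require_entries(cs, COR_NAMES)
  if (n <= 4) abort("`n` must exceed 4.", class = "prospam_error_validation")
  sigma <- cor_set_matrix(cs)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    abort("Target correlation matrix is not positive definite; no smoothing is applied.",
          class = "prospam_error_validation")
  }
  draw <- function() MASS::mvrnorm(n, mu = rep(0, 4), Sigma = sigma, empirical = exact)
  m <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  colnames(m) <- VAR_NAMES
  tibble::as_tibble(m)
}

as_two_wave <- function(data) {
  miss <- setdiff(VAR_NAMES, names(data))
  if (length(miss)) {
    abort(paste0("Two-wave data must carry columns X1, X2, Y1, Y2; missing: ",
                 paste(miss, collapse = ", ")),
          class = "prospam_error_validation")
  }
  out <- tibble::as_tibble(data)[VAR_NAMES]
  if (!all(vapply(out, is.numeric, logical(1))) || !all(vapply(out, function(x) all(is.finite(x)), logical(1)))) {
    abort("Two-wave data must be finite numeric.", class = "prospam_error_validation")
  }
  out
}

#' Sample correlations of a two-wave dataset
#'
#' @param data Data frame with columns `X1`, `X2`, `Y1`, `Y2` (at least 5
#'   rows).
#' @return A [correlation_set()] with `n` attached. A duplicated /
#'   perfectly collinear pair yields a correlation of 1, which the
#'   `cor_set` validity machinery rejects — flagging the degeneracy rather
#'   than silently passing it downstream.
#' @export
sample_correlations <- function(data) {
  data <- as_two_wave(data)
  if (nrow(data) < 5) abort("Need at least 5 rows.", class = "prospam_error_validation")
  sds <- vapply(data, sd, numeric(1))
  if (any(sds == 0)) {
    abort(paste0("Zero-variance column(s): ",
                 paste(VAR_NAMES[sds == 0], collapse = ", ")),
          class = "prospam_error_degenerate")
  }
  m <- cor(as.matrix(data))
  off <- m[upper.tri(m)]
  if (any(abs(off) >= 1 - 1e-12)) {
    abort("Perfectly correlated column pair; the correlation set would be degenerate.",
          class = "prospam_error_degenerate")
  }
  cor_set_from_matrix(m, n = nrow(data))
}

std_beta <- function(y, x, covariate = NULL) {
  ## standardized least-squares coefficient of x in y ~ x (+ covariate)
  if (is.null(covariate)) {
    fit <- lm(y ~ x)
    unname(coef(fit)[2] * sd(x) / sd(y))
  } else {
    fit <- lm(y ~ x + covariate)
    unname(coef(fit)[2] * sd(x) / sd(y))
  }
}

#' Empirical standardized effects from raw two-wave data
#'
#' Least-squares counterpart of [effects_bundle()]: per direction, the
#' forward and reverse adjusted lagged effects, the effect of the time-1
#' predictor on the outcome change score, and the change-on-change effect.
#' Variables are z-scored before difference scores are formed, and every
#' coefficient is standardized by the realized standard deviations, so on
#' data carrying exactly the correlations of a set `cs` this reproduces
#' `effects_bundle(cs)` to machine precision.
#'
#' @param data Data frame with columns `X1`, `X2`, `Y1`, `Y2` (at least 10
#'   rows).
#' @return A tibble shaped like [effects_bundle()].
#' @export
empirical_effects <- function(data) {
  data <- as_two_wave(data)
  if (nrow(data) < 10) abort("Need at least 10 rows.", class = "prospam_error_validation")
  z <- lapply(data, function(v) {
    s <- sd(v)
    if (s == 0) abort("Zero-variance column.", class = "prospam_error_degenerate")
    (v - mean(v)) / s
  })
  qrch <- qr(cbind(1, z$X1, z$Y1))
  if (qrch$rank < 3 || qr(cbind(1, z$Y1, z$Y2))$rank < 3 || qr(cbind(1, z$X1, z$X2))$rank < 3) {
    abort("Collinear predictors in the two-wave design.", class = "prospam_error_degenerate")
  }
  dX <- z$X2 - z$X1
  dY <- z$Y2 - z$Y1
  coc <- std_beta(dY, dX)
  out <- dplyr::bind_rows(
    tibble::tibble(direction = "xy",
                   beta_lag_fwd = std_beta(z$Y2, z$X1, z$Y1),
                   beta_lag_rev = std_beta(z$Y1, z$X1, z$Y2),
                   beta_change = std_beta(dY, z$X1),
                   beta_change_on_change = coc),
    tibble::tibble(direction = "yx",
                   beta_lag_fwd = std_beta(z$X2, z$Y1, z$X1),
                   beta_lag_rev = std_beta(z$X1, z$Y1, z$X2),
                   beta_change = std_beta(dX, z$Y1),
                   beta_change_on_change = coc)
  )
  class(out) <- c("effects_bundle", class(out))
  out
}

repair_correlation_matrix <- function(m, floor = 1e-8) {
  ## nearest-valid repair: clip eigenvalues, renormalize to unit diagonal
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  r <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  diag(r) <- 1
  dimnames(r) <- dimnames(m)
  r
}

#' Generate a synthetic multi-study correlation table
#'
#' Builds `k` study records around a SPAM population: each study's true
#' correlation structure is the population implied matrix perturbed on the
#' Fisher-z scale by `Normal(0, tau_z)` (then repaired to the nearest valid
#' correlation matrix if needed), from which a stochastic sample of size
#' drawn uniformly from `n_range` is simulated and its sample correlations
#' recorded. Designated studies have their time-2 Y entries blanked to
#' emulate studies that never measured the outcome at follow-up.
#'
#' The result has the same shape as a user-transcribed per-study correlation
#' table and is synthetic: it stands in for extracted study tables in tests
#' and examples.
#'
#' @param params Population [spam_params()].
#' @param k Number of studies (at least 2).
#' @param n_range Length-2 integer range of per-study sample sizes.
#' @param tau_z Between-study standard deviation on the Fisher-z scale
#'   (`>= 0`).
#' @param seed Integer seed.
#' @param missing_y2 Indices of studies whose `r_x1y2`, `r_x2y2`, `r_y1y2`
#'   entries are blanked.
#' @return A tibble with columns `study`, `n`, and the six correlations.
#' @export
make_study_fixtures <- function(params, k = 10, n_range = c(150, 800),
                                tau_z = 0.1, seed = 1, missing_y2 = integer()) {
  stopifnot(k >= 2, tau_z >= 0)
  pop <- cor_set_matrix(implied_correlations(params))
  withr::with_seed(as.integer(seed), {
    rows <- purrr::map(seq_len(k), function(i) {
      n_i <- if (n_range[1] == n_range[2]) n_range[1] else sample(seq(n_range[1], n_range[2]), 1)
      target <- NULL
      for (try in 1:20) {
        z <- atanh(pop[upper.tri(pop)]) + rnorm(6, 0, tau_z)
        m <- diag(4)
        m[upper.tri(m)] <- tanh(z)
        m <- m + t(m) - diag(diag(m))
        diag(m) <- 1
        if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8) {
          m <- repair_correlation_matrix(m)
        }
        if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > 1e-8) {
          target <- m
          break
        }
      }
      if (is.null(target)) {
        abort("Could not generate a valid study correlation matrix.",
              class = "prospam_error_validation")
      }
      dimnames(target) <- list(VAR_NAMES, VAR_NAMES)
      dat <- MASS::mvrnorm(n_i, rep(0, 4), target, empirical = FALSE)
      colnames(dat) <- VAR_NAMES
      cs <- sample_correlations(tibble::as_tibble(dat))
      out <- tibble::as_tibble(cs)[COR_NAMES]
      out$study <- paste0("study_", i)
      out$n <- n_i
      out
    })
    studies <- dplyr::bind_rows(rows)[c("study", "n", COR_NAMES)]
    if (length(missing_y2)) {
      studies[missing_y2, c("r_x1y2", "r_x2y2", "r_y1y2")] <- NA_real_
    }
    studies
  })
}
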