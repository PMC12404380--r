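## Independent oracles used across the suite. These deliberately avoid the
## package's own closed forms: partial coefficients come from solving the
## two-predictor normal equations, pooled meta estimates from the
## DerSimonian-Laird closed form, and expected effects from least squares on
## exact-correlation data.

## standardized coefficient of predictor x on outcome y adjusting for z,
## by direct linear solve of the normal equations
oracle_partial_beta <- function(r_xy, r_xz, r_yz) {
  R <- matrix(c(1, r_xz, r_xz, 1), 2, 2)
  drop(solve(R, c(r_xy, r_yz)))[1]
}

## the pooled loneliness / social-anxiety correlations used throughout
lon_sa_set <- function(n = NA_integer_) {
  correlation_set(0.603, 0.493, 0.379, 0.351, 0.552, 0.568, n = n)
}

## random full-rank 4x4 correlation structure (sample correlations of a
## small random normal draw are PD almost surely for n > 4)
random_cor_set <- function(seed, n = 9) {
  withr::with_seed(seed, {
    m <- stats::cor(matrix(stats::rnorm(n * 4), n, 4))
    dimnames(m) <- list(c("X1", "X2", "Y1", "Y2"), c("X1", "X2", "Y1", "Y2"))
    cor_set_from_matrix(m)
  })
}

## DerSimonian-Laird random-effects pooling, closed form
oracle_dl_pool <- function(z, v) {
  w <- 1 / v
  q <- sum(w * z^2) - sum(w * z)^2 / sum(w)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (length(z) - 1)) / C)
  ws <- 1 / (v + tau2)
  pooled_z <- sum(ws * z) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(q = q, tau2 = tau2, pooled_z = pooled_z, se = se,
       pooled = tanh(pooled_z),
       ci_low = tanh(pooled_z - stats::qnorm(0.975) * se),
       ci_high = tanh(pooled_z + stats::qnorm(0.975) * se),
       i2 = max(0, (q - (length(z) - 1)) / q) * 100)
}

## dense grid + coordinate-descent refinement of the ML discrepancy, as an
## optimizer-independent check of fit_spam()
oracle_min_discrepancy <- function(cs, s) {
  S <- cor_set_matrix(cs)
  fval <- function(p) {
    tryCatch({
      sig <- cor_set_matrix(implied_correlations(
        spam_params(a = p[1], s = s, b = p[2], c = p[3], d = p[4]),
        check_psd = FALSE
      ))
      ml_discrepancy(S, sig)
    }, error = function(e) Inf)
  }
  grid <- seq(0.05, 0.95, by = 0.15)
  dgrid <- seq(-0.45, 0.45, by = 0.15)
  best <- Inf
  best_p <- NULL
  for (a in grid) for (b in grid) for (cc in grid) for (d in dgrid) {
    v <- fval(c(a, b, cc, d))
    if (v < best) {
      best <- v
      best_p <- c(a, b, cc, d)
    }
  }
  lo <- c(1e-6, 1e-6, 1e-6, -0.999)
  hi <- c(1 - 1e-6, 1 - 1e-6, 1 - 1e-6, 0.999)
  for (sweep in 1:60) {
    for (j in 1:4) {
      opt <- stats::optimize(function(x) {
        p <- best_p; p[j] <- x; fval(p)
      }, lower = lo[j], upper = hi[j], tol = 1e-10)
      if (opt$objective < best) {
        best <- opt$objective
        best_p[j] <- opt$minimum
      }
    }
  }
  list(F = best, par = best_p)
}

## two-wave generator with a genuine cross-lagged structural effect of X1 on
## Y2 (a recursion, not the trait-state model) for specificity checks
simulate_true_crosslagged <- function(n, beta_xy, stability = 0.6, rho = 0.3,
                                      seed = 1) {
  withr::with_seed(seed, {
    X1 <- stats::rnorm(n)
    Y1 <- rho * X1 + sqrt(1 - rho^2) * stats::rnorm(n)
    X2 <- stability * X1 + sqrt(1 - stability^2) * stats::rnorm(n)
    ey <- stats::rnorm(n)
    Y2 <- stability * Y1 + beta_xy * X1 + ey
    tibble::tibble(X1 = X1, X2 = X2, Y1 = Y1, Y2 = Y2)
  })
}
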