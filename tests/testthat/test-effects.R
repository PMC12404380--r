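test_that("partial_beta matches the normal-equations oracle and its special cases", {
  expect_equal(partial_beta(0.379, 0.493, 0.568),
               oracle_partial_beta(0.379, 0.493, 0.568), tolerance = 1e-12)
  expect_equal(round(partial_beta(0.379, 0.493, 0.568), 4), 0.1308)
  ## numerator vanishes when r_xy = r_xz * r_yz
  expect_equal(partial_beta(0.24, 0.40, 0.60), 0)
  ## uncorrelated covariate leaves the zero-order correlation
  expect_equal(partial_beta(0.50, 0.00, 0.30), 0.50)
  ## property: holds for any inputs with r_xz = 0
  for (seed in 1:20) {
    r <- withr::with_seed(seed, stats::runif(2, -0.95, 0.95))
    expect_equal(partial_beta(r[1], 0, r[2]), r[1])
  }
  expect_error(partial_beta(0.3, 1, 0.2), class = "prospam_error_validation")
})

test_that("lagged effects follow the time-symmetric adjustment formulas", {
  lag <- lagged_effects(lon_sa_set(), "xy")
  expect_equal(unname(lag["beta_lag_fwd"]),
               oracle_partial_beta(0.379, 0.493, 0.568), tolerance = 1e-12)
  ## reverse effect: outcome Y1, predictors X1 and Y2
  expect_equal(unname(lag["beta_lag_rev"]),
               oracle_partial_beta(0.493, 0.379, 0.568), tolerance = 1e-12)
  expect_equal(round(unname(lag), 4), c(0.1308, 0.3243))

  ## no X1-Y correlation at either wave -> both effects vanish
  nil <- correlation_set(0.5, 0, 0, 0.2, 0.3, 0.4)
  expect_equal(unname(lagged_effects(nil, "xy")), c(0, 0))
  ## equal cross-wave correlations and independent outcome waves reduce
  ## termwise to the zero-order correlation
  sym <- correlation_set(0.5, 0.3, 0.3, 0.2, 0.25, 0)
  expect_equal(unname(lagged_effects(sym, "xy")), c(0.3, 0.3) / (1 - 0.09))
  expect_error(lagged_effects(as_correlation_set(list(r_x1x2 = 0.5)), "xy"),
               regexp = "r_x1y1", class = "prospam_error_missing_input")
})

test_that("difference-score effects match their closed forms and symmetries", {
  cs <- lon_sa_set()
  expect_equal(change_effect(cs, "xy"), (0.379 - 0.493) / sqrt(2 * (1 - 0.568)))
  expect_equal(round(change_effect(cs, "xy"), 4), -0.1226)
  expect_equal(round(change_effect(cs, "yx"), 4), -0.1594)
  ## equal cross and concurrent correlation -> null change effect
  eq <- correlation_set(0.5, 0.4, 0.4, 0.3, 0.45, 0.5)
  expect_equal(change_effect(eq, "xy"), 0)

  expect_equal(round(change_on_change_effect(cs), 4), 0.3803)
  ## concurrent equal to cross-lagged -> numerator vanishes
  flat <- correlation_set(0.5, 0.35, 0.35, 0.35, 0.35, 0.5)
  expect_equal(change_on_change_effect(flat), 0)
  ## exact symmetry under exchanging the X and Y roles
  for (seed in 1:25) {
    cs_r <- random_cor_set(seed)
    swapped <- correlation_set(cs_r$r_y1y2, cs_r$r_x1y1, cs_r$r_x2y1,
                               cs_r$r_x1y2, cs_r$r_x2y2, cs_r$r_x1x2)
    expect_equal(change_on_change_effect(cs_r), change_on_change_effect(swapped))
  }
  degenerate <- correlation_set(0.5, 0.3, 0.3, 0.3, 0.3, 1 - 1e-15)
  expect_error(change_effect(degenerate, "xy"), class = "prospam_error_degenerate")
})

test_that("effects_bundle assembles both directions and tolerates missing entries", {
  eb <- effects_bundle(lon_sa_set())
  expect_equal(eb$direction, c("xy", "yx"))
  expect_equal(round(unlist(eb[eb$direction == "xy", -1]), 4),
               c(beta_lag_fwd = 0.1308, beta_lag_rev = 0.3243,
                 beta_change = -0.1226, beta_change_on_change = 0.3803))
  ## identity: change-on-change equal across directions
  expect_identical(eb$beta_change_on_change[1], eb$beta_change_on_change[2])

  ## d = 0 population: no state excess, so both change effects vanish
  eb0 <- effects_bundle(implied_correlations(spam_params(0.7, 1, 0.8, 0.6, 0)))
  expect_equal(eb0$beta_change, c(0, 0))
  expect_equal(eb0$beta_change_on_change, c(0, 0))

  ## missing Y2 correlations: Y2-dependent effects are NA, the rest computed
  part <- as_correlation_set(list(r_x1x2 = 0.6, r_x1y1 = 0.5, r_x2y1 = 0.35))
  ebp <- effects_bundle(part)
  expect_true(all(is.na(unlist(ebp[ebp$direction == "xy", -1]))))
  yx <- ebp[ebp$direction == "yx", ]
  expect_false(anyNA(yx[c("beta_lag_fwd", "beta_lag_rev", "beta_change")]))
  expect_true(is.na(yx$beta_change_on_change))
})

test_that("sign classification reproduces the diagnostic templates", {
  mk <- function(v) tibble::tibble(direction = "xy", beta_lag_fwd = v[1],
                                   beta_lag_rev = v[2], beta_change = v[3],
                                   beta_change_on_change = v[4])
  ## the pooled loneliness/social-anxiety pattern: spurious-positive
  expect_equal(classify_signs(mk(c(0.123, 0.354, -0.145, 0.366)))$verdict,
               "spurious-positive")
  expect_equal(classify_signs(mk(c(0.3, -0.2, 0.25, 0.3)))$verdict, "true-increasing")
  expect_equal(classify_signs(mk(c(-0.3, 0.2, -0.25, -0.3)))$verdict, "true-decreasing")
  expect_equal(classify_signs(mk(c(-0.12, -0.35, 0.15, -0.37)))$verdict,
               "spurious-negative")
  ## all effects inside the zero band
  expect_equal(classify_signs(mk(c(0.01, -0.015, 0.005, 0)))$verdict, "inconclusive")
  ## mixed pattern matching no template
  expect_equal(classify_signs(mk(c(0.3, -0.2, -0.25, 0.3)))$verdict, "inconclusive")
  ## epsilon band is honoured: a 0.05 change effect is "0" at epsilon 0.1
  expect_equal(classify_signs(mk(c(0.3, 0.2, -0.05, 0.25)), epsilon = 0.1)$verdict,
               "spurious-positive")
  ## CI mode: wide standard errors turn small effects into zeros
  se <- mk(c(0.01, 0.01, 0.2, 0.2))
  expect_equal(classify_signs(mk(c(0.2, 0.25, -0.1, 0.15)), se = se)$verdict,
               "spurious-positive")
})

test_that("closed-form effects agree with the SPAM's sign structure", {
  ## d > 0 with positively associated constructs: positive lagged effects,
  ## negative change effect, positive change-on-change (mirrored for s = -1)
  for (s in c(1, -1)) {
    th <- spam_params(a = 0.75, s = s, b = 0.8, c = 0.7, d = s * 0.12)
    eb <- effects_bundle(implied_correlations(th))
    expect_true(all(s * eb$beta_lag_fwd > 0))
    expect_true(all(s * eb$beta_lag_rev > 0))
    expect_true(all(s * eb$beta_change < 0))
    expect_true(all(s * eb$beta_change_on_change > 0))
  }
})
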