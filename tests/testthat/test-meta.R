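test_that("Fisher transform and its inverse behave as a variance-stabilizing pair", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  expect_equal(inv_fisher_z(fisher_z(0.837)), 0.837, tolerance = 1e-12)
  for (r in seq(-0.95, 0.95, by = 0.19)) {
    expect_equal(inv_fisher_z(fisher_z(r)), r, tolerance = 1e-12)
  }
  ## monotone back-transform
  zs <- sort(stats::runif(20, -2, 2))
  expect_identical(order(inv_fisher_z(zs)), seq_along(zs))
  expect_error(fisher_z(1), class = "prospam_error_validation")
})

test_that("per-study effects propagate availability", {
  pop <- spam_params(0.79, 1, 0.777, 0.755, 0.158)
  st <- make_study_fixtures(pop, k = 3, n_range = c(300, 500), tau_z = 0.05,
                            seed = 3, missing_y2 = 2)
  eff <- study_effects(st)
  expect_identical(nrow(eff), 3L * 8L)
  s2 <- eff[eff$study == "study_2", ]
  ## Y2-dependent effects missing, Y2-free effects present
  expect_true(all(is.na(s2$estimate[s2$direction == "xy"])))
  yx2 <- s2[s2$direction == "yx", ]
  expect_false(anyNA(yx2$estimate[yx2$effect != "beta_change_on_change"]))

  ## a study holding exactly the population matrix reproduces the closed forms
  pop_cs <- implied_correlations(pop)
  one <- tibble::tibble(study = "pop", n = 1000)
  one <- dplyr::bind_cols(one, tibble::as_tibble(pop_cs)[1, 1:6])
  eff_pop <- study_effects(one)
  eb <- tidyr::pivot_longer(effects_bundle(pop_cs), cols = dplyr::starts_with("beta_"),
                            names_to = "effect", values_to = "expected")
  merged <- dplyr::left_join(eff_pop, eb, by = c("direction", "effect"))
  expect_equal(merged$estimate, merged$expected, tolerance = 1e-12)
})

test_that("random-effects pooling matches the DerSimonian-Laird oracle", {
  z <- c(0.2, 0.4, 0.9)
  v <- c(0.01, 0.02, 0.05)
  got <- meta_pool(z, v, method = "DL")
  ora <- oracle_dl_pool(z, v)
  expect_equal(got$q, 8.4117647059, tolerance = 1e-9)
  expect_equal(got$tau2, 0.068125, tolerance = 1e-9)
  expect_equal(got$pooled_z, 0.4512923607, tolerance = 1e-9)
  expect_equal(got$pooled, 0.4229607478, tolerance = 1e-9)
  expect_equal(got$ci_low, 0.1076697466, tolerance = 1e-8)
  expect_equal(got$ci_high, 0.6609484706, tolerance = 1e-8)
  expect_equal(got$i2, 76.2237762238, tolerance = 1e-8)
  ## against the closed form recomputed in the helper
  expect_equal(got$tau2, ora$tau2)
  expect_equal(got$pooled_z, ora$pooled_z)
  expect_identical(got$q_df, 2L)

  ## identical studies: no heterogeneity
  same <- meta_pool(rep(0.3, 5), rep(0.02, 5))
  expect_equal(same$pooled, tanh(0.3))
  expect_equal(same$q, 0)
  expect_equal(same$tau2, 0)
  expect_equal(same$i2, 0)

  ## single study passes through with flagged heterogeneity
  one <- meta_pool(0.4, 0.01)
  expect_equal(one$pooled, tanh(0.4))
  expect_true(is.na(one$tau2) && is.na(one$q))
  expect_error(meta_pool(c(0.1, 0.2), c(0.01, 0)), class = "prospam_error_validation")
})

test_that("pooling invariants hold across random configurations", {
  for (seed in 1:10) {
    cfg <- withr::with_seed(seed, list(z = stats::rnorm(7, 0.3, 0.3),
                                       v = stats::runif(7, 0.005, 0.08)))
    got <- meta_pool(cfg$z, cfg$v, method = "REML")
    expect_true(got$i2 >= 0 && got$i2 <= 100)
    expect_gte(got$q, 0)
    expect_true(got$ci_low <= got$pooled && got$pooled <= got$ci_high)
    expect_true(abs(got$pooled) < 1)
    ## order invariance
    perm <- withr::with_seed(seed, sample(7))
    got_p <- meta_pool(cfg$z[perm], cfg$v[perm], method = "REML")
    expect_equal(got_p$pooled, got$pooled, tolerance = 1e-10)
    expect_equal(got_p$tau2, got$tau2, tolerance = 1e-10)
  }
})

test_that("the 14-row meta table mirrors the two-wave synthesis layout", {
  pop <- spam_params(0.75, 1, 0.8, 0.75, 0.12)
  st <- make_study_fixtures(pop, k = 10, n_range = c(200, 700), tau_z = 0.05,
                            seed = 12, missing_y2 = c(4, 9))
  mt <- meta_table(st)
  expect_identical(nrow(mt), 14L)
  expect_identical(sum(mt$kind == "correlation"), 6L)
  ## K pattern: Y2-free rows aggregate all 10 studies, the rest 8
  k_by <- setNames(mt$k, mt$association)
  expect_identical(unname(k_by[c("r_x1x2", "r_x1y1", "r_x2y1")]), rep(10L, 3))
  expect_identical(unname(k_by[c("r_x1y2", "r_x2y2", "r_y1y2")]), rep(8L, 3))
  expect_identical(unname(k_by[c("beta_lag_fwd_yx", "beta_lag_rev_yx", "beta_change_yx")]),
                   rep(10L, 3))
  expect_identical(unname(k_by["beta_lag_fwd_xy"]), 8L)
  ## the change-on-change rows are identical across directions
  r10 <- mt[mt$association == "beta_change_on_change_xy", -1]
  r14 <- mt[mt$association == "beta_change_on_change_yx", -1]
  expect_equal(as.data.frame(r10[-1]), as.data.frame(r14[-1]))
})

test_that("pooled estimates recover the population under no heterogeneity", {
  pop <- spam_params(0.79, 1, 0.777, 0.755, 0.158)
  st <- make_study_fixtures(pop, k = 8, n_range = c(4000, 4000), tau_z = 0,
                            seed = 21)
  mt <- meta_table(st)
  pop_cs <- implied_correlations(pop)
  for (nm in c("r_x1x2", "r_x1y1", "r_x1y2", "r_y1y2")) {
    expect_equal(mt$pooled[mt$association == nm], pop_cs[[nm]], tolerance = 0.02)
  }
  eb <- effects_bundle(pop_cs)
  expect_equal(mt$pooled[mt$association == "beta_lag_fwd_xy"],
               eb$beta_lag_fwd[eb$direction == "xy"], tolerance = 0.02)
  expect_equal(mt$pooled[mt$association == "beta_change_on_change_xy"],
               eb$beta_change_on_change[1], tolerance = 0.03)
})

test_that("REML between-study variance tracks the generating tau_z", {
  tau_z <- 0.1
  reps <- 12
  est <- numeric(0)
  for (r in seq_len(reps)) {
    st <- make_study_fixtures(spam_params(0.75, 1, 0.8, 0.75, 0.1),
                              k = 30, n_range = c(500, 1500), tau_z = tau_z,
                              seed = 100 + r)
    got <- meta_pool(fisher_z(st$r_x1y1), 1 / (st$n - 3), method = "REML")
    est <- c(est, got$tau2)
  }
  expect_lt(abs(mean(est) - tau_z^2) / tau_z^2, 0.5)
})
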