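test_that("zero-noise limit reproduces class mean trajectories exactly", {
  cfg <- sim_config(n_children = 30L, dropout_prob = 0, noise_sd = 0,
                    fixed_effect_sd = 0, sex_effect = 0, seed = 7L,
                    n_modules = 2L, lipids_per_module = 5L)
  sim <- simulate_study(cfg)
  traj <- vapply(cfg$class_spec, function(cl) {
    cl$coef[1] + cl$coef[2] * seq_along(cfg$visit_weeks)
  }, numeric(length(cfg$visit_weeks)))
  for (i in c(1L, 12L, 30L)) {
    rows <- sim$panel[sim$panel$child_id == i, ]
    expect_equal(rows$laz, traj[, sim$truth$class_labels[i]],
                 tolerance = 1e-12)
    expect_equal(rows$waz, rows$laz)
  }
})

test_that("cohort-scale panel has <= n*T rows and full first visits", {
  cfg <- sim_config(n_children = 409L, dropout_prob = 0.15, seed = 2L,
                    n_modules = 2L, lipids_per_module = 5L)
  sim <- simulate_study(cfg)
  expect_lte(nrow(sim$panel), 409L * 5L)
  expect_lt(nrow(sim$panel), 409L * 5L)  # some dropout occurred
  expect_equal(sum(sim$panel$visit_index == 1L), 409L)
  # missingness only from dropout: every child retains visit 1
  expect_setequal(unique(sim$panel$child_id), 1:409)
})

test_that("within-module correlation matches its target", {
  cfg <- sim_config(n_children = 400L, dropout_prob = 0, seed = 5L,
                    n_modules = 2L, lipids_per_module = 20L,
                    within_module_cor = 0.81)
  sim <- simulate_study(cfg)  # 2000 samples
  cols <- names(sim$truth$module_assignment)[
    sim$truth$module_assignment == 1L]
  cc <- cor(as.matrix(sim$panel[, cols]))
  expect_equal(mean(cc[upper.tri(cc)]), 0.81, tolerance = 0.03)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(class_spec = list(list(prop = 0.7, coef = 0),
                                            list(prop = 0.7, coef = 0))),
               "sum to 1")
  expect_error(sim_config(visit_weeks = c(12, 12, 52)), "increasing")
  k <- 13L
  expect_error(sim_config(var_matrix = diag(1.2, k)), "unstable")
  expect_silent(validate_sim <- sim_config(var_matrix = diag(1.2, k),
                                           require_stable = FALSE))
  expect_error(simulate_var_panel(10, 5, matrix(1.5, 1, 1)), "unstable")
})

test_that("pure VAR panel: white noise, determinism, Nickell attenuation", {
  p0 <- simulate_var_panel(300, 5, matrix(0, 1, 1), fe_sd = 0,
                           noise_sd = 1, seed = 3L)
  wide <- matrix(p0$y1, ncol = 5, byrow = TRUE)
  ac <- cor(as.vector(wide[, -5]), as.vector(wide[, -1]))
  expect_lt(abs(ac), 3 / sqrt(300 * 5))

  expect_identical(simulate_var_panel(50, 4, matrix(0.5, 1, 1), seed = 9L),
                   simulate_var_panel(50, 4, matrix(0.5, 1, 1), seed = 9L))

  p1 <- simulate_var_panel(500, 5, matrix(0.5, 1, 1), fe_sd = 1,
                           noise_sd = 1, seed = 4L)
  p1$ylag <- ave(p1$y1, p1$child_id,
                 FUN = function(v) c(NA, head(v, -1)))
  fit <- within_fe_fit(p1, "y1", "ylag")
  # within estimator biased to about rho - (1+rho)/(T-1) = 0.125
  expect_lt(fit$coefficients$estimate[1], 0.3)
  expect_gt(fit$coefficients$estimate[1], -0.05)
})

test_that("stationarity after burn-in: variance stable over time", {
  p <- simulate_var_panel(2000, 6, matrix(0.6, 1, 1), fe_sd = 0,
                          noise_sd = 1, seed = 6L)
  v_by_t <- tapply(p$y1, p$visit_index, var)
  expect_lt(max(v_by_t) / min(v_by_t), 1.2)
})

test_that("fixed effects cancel under differencing transforms", {
  x <- c(1.3, 2.1, 0.4, 1.9)
  expect_equal(fod_transform(x + 5), fod_transform(x), tolerance = 1e-12)
  expect_equal(diff(x + 5), diff(x), tolerance = 1e-12)
})

test_that("class-conditional growth means converge to the trajectories", {
  cfg <- sim_config(n_children = 5000L, dropout_prob = 0, seed = 8L,
                    n_modules = 2L, lipids_per_module = 4L,
                    sex_effect = 0, noise_sd = 0.4, fixed_effect_sd = 0.4)
  sim <- simulate_study(cfg)
  cls <- sim$truth$class_labels[sim$panel$child_id]
  for (g in seq_along(cfg$class_spec)) {
    cl <- cfg$class_spec[[g]]
    for (t in c(1L, 5L)) {
      sel <- cls == g & sim$panel$visit_index == t
      target <- cl$coef[1] + cl$coef[2] * t
      se <- sd(sim$panel$laz[sel]) / sqrt(sum(sel))
      expect_lt(abs(mean(sim$panel$laz[sel]) - target), 3 * se + 1e-9)
    }
  }
})

test_that("raw feature generator honours its violation contracts", {
  clean <- simulate_raw_features(8, 25, seed = 1L)
  res <- apply_qc_filters(clean$raw)
  expect_true(all(res$report$pass_overall))

  vs <- list(ppm = 1L, blank = 2L, zero = 3L, dilution = 4L)
  sr <- simulate_raw_features(10, 30, violation_spec = vs, seed = 2L)
  m <- compute_qc_metrics(sr$raw)
  expect_gt(m$ppm_deviation[1], 5)
  expect_lt(m$blank_ratio[2], 5)
  expect_gt(m$zero_fraction[3], 0.10)
  expect_lt(m$dilution_r[4], 0.9)
  expect_equal(sum(apply_qc_filters(sr$raw)$report$pass_overall), 6L)

  expect_error(simulate_raw_features(5, 12, seed = 1L), "too small")
})
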