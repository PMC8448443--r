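test_that("forward orthogonal deviations match the closed form", {
  out <- fod_transform(c(1, 2, 4))
  expect_equal(out[1], sqrt(2 / 3) * (1 - 3), tolerance = 1e-10)
  expect_equal(out[2], sqrt(1 / 2) * (2 - 4), tolerance = 1e-10)
  expect_true(is.na(out[3]))

  expect_equal(fod_transform(c(5, 5, 5))[1:2], c(0, 0))
  x <- c(0.3, NA, 1.2, -0.5)                 # gap: future mean over
  expect_equal(fod_transform(x)[1],          # available obs only
               sqrt(2 / 3) * (0.3 - mean(c(1.2, -0.5))))
  expect_equal(fod_transform(x + 7), fod_transform(x), tolerance = 1e-12)
})

test_that("instrument layout matches hand enumeration for tiny panels", {
  pan <- gen_exact_var_panel(12, 3, 0.5, seed = 1)
  sys <- build_gmm_system(pan, pvar_spec("y1", transform = "fd",
                                         system = FALSE))
  # k=1, p=1, T=3, fd: only y_{i1} instruments the t=3 difference
  expect_equal(ncol(sys$Z), 1L)
  expect_equal(unname(sys$Z[, 1]), pan$y1[pan$visit_index == 1])

  # fod with T=3: rows t=2 (instrument y1); t=3 has no future values
  sys2 <- build_gmm_system(pan, pvar_spec("y1", transform = "fod",
                                          system = FALSE))
  expect_equal(unique(sys2$period), 2L)
  expect_equal(ncol(sys2$Z), 1L)

  expect_error(build_gmm_system(pan[pan$visit_index <= 2, ],
                                pvar_spec("y1")), "at least 3 periods")
})

test_that("missing visits zero-fill instruments but keep usable rows", {
  pan <- gen_exact_var_panel(8, 4, 0.5, seed = 2)
  pan <- pan[!(pan$child_id == 1 & pan$visit_index == 1), ]  # gap child 1
  sys <- build_gmm_system(pan, pvar_spec("y1", transform = "fd",
                                         system = FALSE))
  # child 1 keeps its t=4 row (regressor y3-y2 exists); its y1 entry is 0
  r <- which(sys$child == 1 & sys$period == 4)
  expect_length(r, 1L)
  y1_cols <- grep("^L3_y1_t4$", colnames(sys$Z))
  expect_identical(unname(sys$Z[r, y1_cols]), 0)
  # child 1 has no t=3 row (its differenced regressor needs y1)
  expect_false(any(sys$child == 1 & sys$period == 3))
})

test_that("noise-free dynamics are recovered exactly", {
  a <- matrix(c(0.6, 0.15, -0.1, 0.4), 2, 2)
  pan <- gen_exact_var_panel(40, 4, a, seed = 3)
  fit <- fit_pvar(pan, pvar_spec(c("y1", "y2"), transform = "fd",
                                 system = FALSE))
  expect_equal(unname(fit$A[[1]]), a, tolerance = 1e-8)
  fit2 <- fit_pvar(pan, pvar_spec(c("y1", "y2"), transform = "fod",
                                  system = FALSE))
  expect_equal(unname(fit2$A[[1]]), a, tolerance = 1e-8)
})

test_that("just-identified GMM equals the 2SLS closed form", {
  pan <- simulate_var_panel(200, 3, matrix(0.5, 1, 1), fe_sd = 1,
                            noise_sd = 1, seed = 4)
  fit <- fit_pvar(pan, pvar_spec("y1", transform = "fd", system = FALSE))
  # independent oracle: single instrument y_1 for dy_3 = a dy_2 + e
  w <- reshape(pan, idvar = "child_id", timevar = "visit_index",
               direction = "wide")
  z <- w$y1.1; dy3 <- w$y1.3 - w$y1.2; dy2 <- w$y1.2 - w$y1.1
  expect_equal(unname(fit$A[[1]][1, 1]), sum(z * dy3) / sum(z * dy2),
               tolerance = 1e-10)
  h <- hansen_j(fit)
  expect_equal(h$df, 0L)
  expect_equal(h$J, 0)
  expect_true(is.na(h$p))
  expect_true(h$just_identified)
})

test_that("system GMM corrects the Nickell bias (single panel)", {
  pan <- simulate_var_panel(500, 5, matrix(0.5, 1, 1), fe_sd = 1,
                            noise_sd = 1, seed = 5)
  pan$ylag <- ave(pan$y1, pan$child_id, FUN = function(v) c(NA, head(v, -1)))
  within <- within_fe_fit(pan, "y1", "ylag")$coefficients$estimate
  gmm <- fit_pvar(pan, pvar_spec("y1", transform = "fod",
                                 system = TRUE))$A[[1]][1, 1]
  expect_lt(within, 0.3)          # attenuated well below 0.5
  expect_lt(abs(gmm - 0.5), 0.1)  # GMM approximately unbiased
})

test_that("fod and fd system estimates agree on large balanced panels", {
  pan <- simulate_var_panel(2000, 5, matrix(0.5, 1, 1), fe_sd = 1,
                            noise_sd = 1, seed = 6)
  g1 <- fit_pvar(pan, pvar_spec("y1", transform = "fod"))$A[[1]][1, 1]
  g2 <- fit_pvar(pan, pvar_spec("y1", transform = "fd"))$A[[1]][1, 1]
  expect_lt(abs(g1 - g2), 0.02)
})

test_that("results are equivariant under variable reordering", {
  a <- matrix(c(0.5, 0.2, 0, 0.3), 2, 2)
  pan <- simulate_var_panel(300, 5, a, fe_sd = 1, noise_sd = 1, seed = 7)
  f12 <- fit_pvar(pan, pvar_spec(c("y1", "y2"), transform = "fod"))
  f21 <- fit_pvar(pan, pvar_spec(c("y2", "y1"), transform = "fod"))
  expect_equal(f12$A[[1]][c("y1", "y2"), c("lag1_y1", "lag1_y2")],
               f21$A[[1]][c("y1", "y2"), c("lag1_y1", "lag1_y2")],
               tolerance = 1e-8)
})

test_that("lag selection table follows the Andrews-Lu formulas and ties", {
  pan <- simulate_var_panel(250, 5, matrix(0.5, 1, 1), fe_sd = 1,
                            noise_sd = 1, seed = 8)
  sel <- mmsc_lag_select(pan, pvar_spec("y1", transform = "fod"),
                         p_candidates = c(1, 2))
  cr <- sel$criteria
  expect_equal(cr$MMSC_BIC, cr$J - (cr$c - cr$b) * log(cr$N))
  expect_equal(cr$MMSC_AIC, cr$J - 2 * (cr$c - cr$b))
  expect_equal(cr$MMSC_HQIC, cr$J - 2.1 * (cr$c - cr$b) * log(log(cr$N)))
  # tie in the criterion resolves to the smaller order
  cr2 <- cr; cr2$MMSC_BIC <- c(1, 1)
  expect_equal(cr$p[which.min(cr2$MMSC_BIC)], 1)
})

test_that("stability analytics are exact on analytic cases", {
  s <- stability_check(diag(c(0.5, 0.3)))
  expect_setequal(round(s$moduli, 12), c(0.5, 0.3))
  expect_true(s$stable)

  s2 <- stability_check(matrix(c(1.2, 0, 0, 0.4), 2, 2))
  expect_false(s2$stable)

  # order-2 companion eigenvalues match the characteristic polynomial
  a1 <- 0.5; a2 <- 0.2
  s3 <- stability_check(list(matrix(a1, 1, 1), matrix(a2, 1, 1)))
  roots <- 1 / polyroot(c(1, -a1, -a2))
  expect_equal(sort(Mod(s3$eigenvalues)), sort(Mod(roots)),
               tolerance = 1e-8)
})

test_that("temporal network extraction respects alpha and signs", {
  k <- 3
  fake <- structure(list(
    A = list(matrix(c(0.5, 0, 0, 0, 0.4, 0, -0.3, 0, 0.2), k, k,
                    dimnames = list(c("waz", "laz", "wlz"), NULL))),
    p_values = matrix(c(0.001, 0.9, 0.02,
                        0.7, 0.01, 0.9,
                        0.8, 0.6, 0.2), k, k,
                      dimnames = list(paste0("lag1_", c("waz", "laz",
                                                        "wlz")),
                                      c("waz", "laz", "wlz"))),
    spec = list(endogenous = c("waz", "laz", "wlz"), lags = 1L)),
    class = "pvar_model")
  net <- extract_temporal_network(fake, alpha = 0.05)
  expect_equal(nrow(net$edges), 3L)
  e <- net$edges
  expect_true(all(e$p_value < 0.05))
  self <- e[e$source == "waz" & e$target == "waz", ]
  expect_equal(self$weight, 0.5)
  cross <- e[e$source == "wlz" & e$target == "waz", ]
  expect_equal(cross$sign, "negative")

  fake$p_values[] <- 0.5
  expect_equal(nrow(extract_temporal_network(fake)$edges), 0L)
})
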