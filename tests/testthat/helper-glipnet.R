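# shared fixture builders (all data generated in code)

# planted-block lipid matrix: `blocks` modules of `per` features, pairwise
# within-module correlation r, zero between modules
gen_planted_blocks <- function(n, per = 20L, blocks = 3L, r = 0.8,
                               seed = 1L) {
  set.seed(seed)
  z <- matrix(rnorm(n * blocks), n, blocks)
  x <- matrix(rnorm(n * per * blocks, sd = sqrt(1 - r)), n, per * blocks)
  x <- x + sqrt(r) * z[, rep(seq_len(blocks), each = per)]
  colnames(x) <- sprintf("lip_%02d", seq_len(ncol(x)))
  x
}

# exact dynamic panel: y_t = a y_{t-1} + v_i, zero idiosyncratic error,
# random (non-stationary) start so differences are informative
gen_exact_var_panel <- function(n, t, a, seed = 1L) {
  if (!is.matrix(a)) a <- matrix(a, 1L, 1L)
  set.seed(seed)
  k <- nrow(a)
  v <- matrix(rnorm(n * k), n, k)
  y <- array(0, c(n, t, k))
  cur <- matrix(rnorm(n * k, sd = 2), n, k)
  for (tt in seq_len(t)) {
    cur <- cur %*% t(a) + v
    y[, tt, ] <- cur
  }
  out <- data.frame(child_id = rep(seq_len(n), times = t),
                    visit_index = rep(seq_len(t), each = n))
  for (j in seq_len(k)) out[[paste0("y", j)]] <- as.vector(y[, , j])
  out[order(out$child_id, out$visit_index), ]
}

# small growth panel with additive child effects, used by the panel-model
# oracle tests
gen_fe_panel <- function(n_children = 20L, t = 5L, betas = c(x1 = 0.5),
                         noise_sd = 1, seed = 1L) {
  set.seed(seed)
  d <- expand.grid(child_id = seq_len(n_children), visit_index = seq_len(t))
  d <- d[order(d$child_id, d$visit_index), ]
  alpha <- rnorm(n_children, sd = 2)
  y <- alpha[d$child_id]
  for (v in names(betas)) {
    d[[v]] <- rnorm(nrow(d))
    y <- y + betas[[v]] * d[[v]]
  }
  d$y <- y + rnorm(nrow(d), sd = noise_sd)
  d
}

# least-squares-dummy-variable oracle for the within estimator
lsdv_oracle <- function(panel, response, covariates) {
  f <- stats::as.formula(paste(
    response, "~ 0 + factor(child_id) +",
    paste(covariates, collapse = " + ")))
  stats::coef(stats::lm(f, data = panel))[covariates]
}

# latent-class world used by the recovery tests: three class trajectories
# separated by >= 3x the child-level standard deviation, no cross-lagged
# dynamics (the latent-class model's own data-generating process)
lcmm_world <- function(n_children = 400L, seed = 1L) {
  k <- 13L
  sim_config(
    n_children = n_children, dropout_prob = 0.1, seed = seed,
    var_matrix = matrix(0, k, k),
    class_spec = list(
      list(prop = 0.3, coef = c(-2.5, -0.10)),
      list(prop = 0.3, coef = c(0.9, -0.30)),
      list(prop = 0.4, coef = c(-0.8, -0.55))
    ),
    noise_sd = 0.25, fixed_effect_sd = 0.25
  )
}
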