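#' Simulation configuration for a synthetic infant cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator:
#' panel dimensions, visit schedule, dropout, latent growth classes, lipid
#' module structure, and the VAR(1) dynamics that couple growth z-scores to
#' module-level lipid signals.
#'
#' The defaults describe a cohort of 409 children seen at 12, 24, 52, 78 and
#' 104 weeks, three latent growth classes with declining z-score
#' trajectories, ten lipid modules of 20 tightly correlated features each,
#' and a stable cross-lagged VAR(1) between the three growth scores and the
#' module latent signals.
#'
#' @param n_children Number of children in the cohort.
#' @param visit_weeks Strictly increasing integer vector of visit weeks.
#' @param dropout_prob Per-visit probability (after the first visit) that a
#'   child's record is missing; missing-at-random Bernoulli.
#' @param seed Integer seed; identical configurations give identical output.
#' @param n_modules Number of lipid modules.
#' @param lipids_per_module Features per module.
#' @param within_module_cor Target pairwise Pearson correlation between two
#'   lipids of the same module, in (0, 1).
#' @param noise_sd Standard deviation of the VAR innovation driving the
#'   growth/module state (0 gives deterministic class trajectories).
#' @param var_matrix Square lag-1 coefficient matrix for the stacked state
#'   (WAZ, LAZ, WLZ, module signals); dimension `3 + n_modules`.
#' @param fixed_effect_sd Standard deviation of child-level fixed effects in
#'   the VAR state.
#' @param class_spec List with one element per latent class; each element is
#'   a list with `prop` (mixing proportion) and `coef` (trajectory: either a
#'   vector of per-visit means of length `length(visit_weeks)`, or polynomial
#'   coefficients in the visit index, lowest order first).
#' @param sex_effect Additive shift of the growth mean for `sex == 1`
#'   children (sex is Bernoulli(0.5) at the child level).
#' @param require_stable Reject `var_matrix` with spectral radius >= 1.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_children = 409L,
                       visit_weeks = c(12L, 24L, 52L, 78L, 104L),
                       dropout_prob = 0.1,
                       seed = 1L,
                       n_modules = 10L,
                       lipids_per_module = 20L,
                       within_module_cor = 0.8,
                       noise_sd = 0.5,
                       var_matrix = NULL,
                       fixed_effect_sd = 0.5,
                       class_spec = default_class_spec(),
                       sex_effect = 0.1,
                       require_stable = TRUE) {
  k <- 3L + as.integer(n_modules)
  if (is.null(var_matrix)) {
    var_matrix <- diag(0.4, k)
    # mild cross-lagged structure among the growth block, mirroring the
    # wasting -> stunting ordering seen in growth-faltering cohorts
    var_matrix[2, 3] <- 0.15  # WLZ_t-1 -> LAZ_t
    var_matrix[3, 1] <- 0.15  # WAZ_t-1 -> WLZ_t
  }
  cfg <- structure(list(
    n_children = as.integer(n_children),
    visit_weeks = as.integer(visit_weeks),
    dropout_prob = dropout_prob,
    seed = as.integer(seed),
    n_modules = as.integer(n_modules),
    lipids_per_module = as.integer(lipids_per_module),
    within_module_cor = within_module_cor,
    noise_sd = noise_sd,
    var_matrix = var_matrix,
    fixed_effect_sd = fixed_effect_sd,
    class_spec = class_spec,
    sex_effect = sex_effect,
    require_stable = isTRUE(require_stable)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default latent-class specification
#'
#' Three classes patterned on LAZ trajectories commonly seen in
#' growth-faltering cohorts: a persistently low class, a high-but-declining
#' class, and a mid-level class with a steep decline, with mixing
#' proportions 0.25 / 0.32 / 0.43.
#'
#' @return List of per-class `prop` / `coef` entries (coef are polynomial
#'   coefficients in the visit index).
#' @export
default_class_spec <- function() {
  list(
    list(prop = 0.25, coef = c(-1.9, -0.05)),
    list(prop = 0.32, coef = c(0.6, -0.30)),
    list(prop = 0.43, coef = c(-0.1, -0.45))
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_children >= 1L, length(cfg$visit_weeks) >= 2L)
  if (any(diff(cfg$visit_weeks) <= 0)) {
    stop("visit_weeks must be strictly increasing")
  }
  if (cfg$dropout_prob < 0 || cfg$dropout_prob >= 1) {
    stop("dropout_prob must be in [0, 1)")
  }
  props <- vapply(cfg$class_spec, function(cl) cl$prop, numeric(1))
  if (abs(sum(props) - 1) > 1e-8) {
    stop("class proportions must sum to 1 (got ", sum(props), ")")
  }
  k <- 3L + cfg$n_modules
  if (!is.matrix(cfg$var_matrix) || nrow(cfg$var_matrix) != k ||
      ncol(cfg$var_matrix) != k) {
    stop("var_matrix must be a ", k, " x ", k, " matrix")
  }
  if (cfg$require_stable) {
    rho <- max(Mod(eigen(cfg$var_matrix, only.values = TRUE)$values))
    if (rho >= 1) {
      stop("var_matrix is unstable (spectral radius ", signif(rho, 4),
           " >= 1); set require_stable = FALSE to override")
    }
  }
  if (cfg$within_module_cor <= 0 || cfg$within_module_cor >= 1) {
    stop("within_module_cor must lie in (0, 1)")
  }
  if (cfg$noise_sd < 0 || cfg$fixed_effect_sd < 0) {
    stop("noise_sd and fixed_effect_sd must be nonnegative")
  }
  invisible(cfg)
}

class_trajectory <- function(coef, visit_weeks) {
  tt <- seq_along(visit_weeks)
  if (length(coef) == length(visit_weeks)) {
    return(as.numeric(coef))
  }
  # polynomial in visit index, lowest order first
  sapply(tt, function(t) sum(coef * t^(seq_along(coef) - 1L)))
}

#' Simulate a longitudinal lipidome-growth cohort with known ground truth
#'
#' Generates a long-format cohort panel in which (a) each child's growth
#' z-scores follow its latent-class mean trajectory plus a child-level
#' random component and noise, (b) the stacked deviations
#' (WAZ, LAZ, WLZ, module latent signals) evolve as a stationary VAR(1)
#' with child fixed effects and coefficient matrix `config$var_matrix`,
#' (c) each lipid feature equals its module's standardized latent signal
#' attenuated to achieve the target within-module correlation plus
#' independent noise, and (d) visits after the first are dropped
#' independently with probability `dropout_prob`.
#'
#' @param config A [sim_config()] object.
#' @return A list with `panel` (data.frame: child_id, sex, week,
#'   visit_index, waz, laz, wlz, lipid_*) and `truth` (class labels, the
#'   true lag-1 matrix, module assignment, fixed effects, latent module
#'   signals).
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_children
  tw <- config$visit_weeks
  tt <- length(tw)
  k <- 3L + config$n_modules

  props <- vapply(config$class_spec, function(cl) cl$prop, numeric(1))
  classes <- sample.int(length(props), n, replace = TRUE, prob = props)
  sex <- stats::rbinom(n, 1L, 0.5)
  fe <- matrix(stats::rnorm(n * k, sd = config$fixed_effect_sd), n, k)

  # stationary VAR(1) state with burn-in
  state <- simulate_var_state(n, tt, config$var_matrix, fe,
                              config$noise_sd, burn_in = 50L)

  traj <- vapply(config$class_spec, function(cl) {
    class_trajectory(cl$coef, tw)
  }, numeric(tt))  # tt x K

  growth <- array(0, c(n, tt, 3L))
  for (g in 1:3) {
    growth[, , g] <- traj[, classes, drop = FALSE] |> t()
    growth[, , g] <- growth[, , g] + state[, , g] + config$sex_effect * sex
  }

  # lipid layer: standardized module latent signal, attenuated
  r <- config$within_module_cor
  n_lip <- config$n_modules * config$lipids_per_module
  module_of <- rep(seq_len(config$n_modules), each = config$lipids_per_module)
  signal <- matrix(0, n * tt, config$n_modules)
  for (q in seq_len(config$n_modules)) {
    z <- as.vector(state[, , 3L + q])
    s <- stats::sd(z)
    signal[, q] <- if (s > 0) (z - mean(z)) / s else 0
  }
  lipids <- matrix(stats::rnorm(n * tt * n_lip, sd = sqrt(1 - r)),
                   n * tt, n_lip)
  lipids <- lipids + sqrt(r) * signal[, module_of, drop = FALSE]
  colnames(lipids) <- sprintf("lipid_%03d", seq_len(n_lip))

  panel <- data.frame(
    child_id = rep(seq_len(n), times = tt),
    sex = rep(sex, times = tt),
    week = rep(tw, each = n),
    visit_index = rep(seq_len(tt), each = n),
    waz = as.vector(growth[, , 1]),
    laz = as.vector(growth[, , 2]),
    wlz = as.vector(growth[, , 3])
  )
  panel <- cbind(panel, as.data.frame(lipids))

  keep <- rep(TRUE, nrow(panel))
  if (config$dropout_prob > 0) {
    later <- panel$visit_index > 1L
    keep[later] <- stats::rbinom(sum(later), 1L, 1 - config$dropout_prob) == 1L
  }
  panel <- panel[keep, , drop = FALSE]
  panel <- panel[order(panel$child_id, panel$visit_index), , drop = FALSE]
  rownames(panel) <- NULL

  truth <- list(
    class_labels = classes,
    a1 = config$var_matrix,
    module_assignment = stats::setNames(module_of, colnames(lipids)),
    fixed_effects = fe,
    latent_signals = signal,
    sex = sex
  )
  list(panel = panel, truth = truth)
}

# state[, t, ] = A state[, t-1, ] + fe + e; burn-in before retaining tt steps
simulate_var_state <- function(n, tt, a, fe, noise_sd, burn_in = 50L) {
  k <- nrow(a)
  state <- array(0, c(n, tt, k))
  cur <- matrix(0, n, k)
  total <- burn_in + tt
  for (step in seq_len(total)) {
    e <- matrix(stats::rnorm(n * k, sd = noise_sd), n, k)
    cur <- cur %*% t(a) + fe + e
    if (step > burn_in) state[, step - burn_in, ] <- cur
  }
  state
}

#' Simulate a pure VAR(1) panel with child fixed effects
#'
#' A bare dynamic panel (no growth classes, no lipid layer) for estimator
#' testing: `y_it = A y_{i,t-1} + v_i + e_it`, initialized at stationarity
#' via a burn-in of at least 50 periods.
#'
#' @param n Number of children (cross-sectional units).
#' @param t Number of retained periods (>= 3).
#' @param a Square lag-1 coefficient matrix (a scalar is promoted to 1x1).
#' @param fe_sd Standard deviation of the child fixed effects.
#' @param noise_sd Innovation standard deviation.
#' @param seed Integer seed.
#' @param require_stable Reject `a` with spectral radius >= 1.
#' @return Long data.frame: child_id, visit_index, y1..yk.
#' @export
simulate_var_panel <- function(n, t, a, fe_sd = 1, noise_sd = 1, seed = 1L,
                               require_stable = TRUE) {
  if (!is.matrix(a)) a <- matrix(a, 1L, 1L)
  stopifnot(nrow(a) == ncol(a), t >= 3L)
  if (require_stable) {
    rho <- max(Mod(eigen(a, only.values = TRUE)$values))
    if (rho >= 1) {
      stop("coefficient matrix is unstable (spectral radius ",
           signif(rho, 4), " >= 1)")
    }
  }
  set.seed(seed)
  k <- nrow(a)
  fe <- matrix(stats::rnorm(n * k, sd = fe_sd), n, k)
  state <- simulate_var_state(n, t, a, fe, noise_sd, burn_in = 50L)
  out <- data.frame(
    child_id = rep(seq_len(n), times = t),
    visit_index = rep(seq_len(t), each = n)
  )
  for (j in seq_len(k)) out[[paste0("y", j)]] <- as.vector(state[, , j])
  out[order(out$child_id, out$visit_index), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Simulate a raw lipid feature table with engineered QC violations
#'
#' Builds a feature-by-sample intensity table containing study samples,
#' blank samples, and a QC dilution series, with feature metadata (expected
#' and mean observed mass). Features named in `violation_spec` are
#' constructed to fail exactly one of the four quality filters
#' (mass deviation > 5 ppm; study/blank intensity ratio < 5; zero fraction
#' > 10 percent; dilution-series correlation r < 0.9); all other features
#' pass all filters.
#'
#' @param n_features Number of features.
#' @param n_samples Total samples including blanks and the dilution series.
#' @param violation_spec Named list with optional elements `ppm`, `blank`,
#'   `zero`, `dilution`, each an integer vector of feature indices to break
#'   for that filter (sets may overlap).
#' @param seed Integer seed.
#' @param n_blanks Number of blank samples (default 3).
#' @param n_dilution Number of QC dilution points (default 5; must be >= 4).
#' @return List with `raw` (a `raw_feature_table`) and `truth` (per-feature
#'   expected pass flags per filter and overall).
#' @export
simulate_raw_features <- function(n_features, n_samples,
                                  violation_spec = list(), seed = 1L,
                                  n_blanks = 3L, n_dilution = 5L) {
  if (n_dilution < 4L) stop("need a dilution series of >= 4 points")
  n_study <- n_samples - n_blanks - n_dilution
  if (n_study < 10L) {
    stop("n_samples too small: need >= ", n_blanks + n_dilution + 10L,
         " samples to host blanks, a ", n_dilution,
         "-point dilution series and >= 10 study samples")
  }
  bad <- function(nm) {
    idx <- violation_spec[[nm]]
    if (is.null(idx)) integer(0) else as.integer(idx)
  }
  set.seed(seed)
  roles <- c(rep("study", n_study), rep("blank", n_blanks),
             rep("qc_dilution", n_dilution))
  dilution <- c(rep(NA_real_, n_study + n_blanks),
                2^-(seq_len(n_dilution) - 1L))

  expected_mass <- stats::runif(n_features, 400, 1000)
  ppm_dev <- stats::runif(n_features, 0.5, 2.5)       # passing: well under 5
  ppm_dev[bad("ppm")] <- stats::runif(length(bad("ppm")), 8, 20)
  observed_mass <- expected_mass * (1 + ppm_dev * 1e-6)

  base <- stats::runif(n_features, 500, 2000)
  x <- matrix(0, n_features, n_samples)
  study_cols <- which(roles == "study")
  blank_cols <- which(roles == "blank")
  qc_cols <- which(roles == "qc_dilution")
  for (f in seq_len(n_features)) {
    x[f, study_cols] <- base[f] * exp(stats::rnorm(n_study, sd = 0.1))
    x[f, blank_cols] <- base[f] / 20 * exp(stats::rnorm(n_blanks, sd = 0.1))
    x[f, qc_cols] <- base[f] * dilution[qc_cols] *
      exp(stats::rnorm(n_dilution, sd = 0.02))
  }
  for (f in bad("blank")) {  # ratio around 2, clearly below 5
    x[f, blank_cols] <- mean(x[f, study_cols]) / 2 *
      exp(stats::rnorm(n_blanks, sd = 0.02))
  }
  for (f in bad("zero")) {   # 20% zeros among study samples
    nz <- max(1L, ceiling(0.2 * n_study))
    x[f, sample(study_cols, nz)] <- 0
  }
  for (f in bad("dilution")) {  # perfectly anti-proportional: r = -1
    x[f, qc_cols] <- base[f] * (max(dilution[qc_cols]) +
                                  min(dilution[qc_cols]) - dilution[qc_cols])
  }

  raw <- raw_feature_table(
    intensities = x,
    feature_meta = data.frame(
      feature = sprintf("feat_%03d", seq_len(n_features)),
      expected_mass = expected_mass,
      observed_mass = observed_mass
    ),
    sample_meta = data.frame(
      sample = sprintf("s%03d", seq_len(n_samples)),
      role = roles,
      dilution_factor = dilution
    )
  )
  pass <- data.frame(
    feature = raw$feature_meta$feature,
    ppm = !(seq_len(n_features) %in% bad("ppm")),
    blank_ratio = !(seq_len(n_features) %in% bad("blank")),
    zero_fraction = !(seq_len(n_features) %in% bad("zero")),
    dilution_r = !(seq_len(n_features) %in% bad("dilution"))
  )
  pass$overall <- pass$ppm & pass$blank_ratio & pass$zero_fraction &
    pass$dilution_r
  list(raw = raw, truth = pass)
}
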