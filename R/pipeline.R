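#' Read a cohort panel from CSV
#'
#' Validates the documented long-format schema: mandatory columns
#' `child_id`, `sex`, `week`, growth z-scores `waz`/`laz`/`wlz`, and any
#' number of `lipid_*` or `me_*` feature columns. Weeks are mapped to visit
#' indices 1..T by their rank in the sorted unique schedule (so week 52 of
#' the standard 12/24/52/78/104 schedule becomes visit 3). Duplicate
#' (child, week) rows are rejected; growth z-scores outside [-6, 6] are
#' flagged with a warning.
#'
#' @param path CSV file path.
#' @return data.frame cohort panel with a `visit_index` column.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  mandatory <- c("child_id", "sex", "week", "waz", "laz", "wlz")
  miss <- setdiff(mandatory, names(d))
  if (length(miss)) {
    stop("cohort CSV is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(d[, c("child_id", "week")])) {
    dup <- d[duplicated(d[, c("child_id", "week")]), c("child_id", "week")]
    stop("duplicate (child_id, week) rows, e.g. child ", dup$child_id[1L],
         " week ", dup$week[1L])
  }
  weeks <- sort(unique(d$week))
  d$visit_index <- match(d$week, weeks)
  z <- as.matrix(d[, c("waz", "laz", "wlz")])
  bad <- sum(abs(z) > 6, na.rm = TRUE)
  if (bad > 0L) {
    warning(bad, " growth z-score(s) outside [-6, 6]; check input units")
  }
  d[order(d$child_id, d$visit_index), , drop = FALSE] |>
    (\(x) { rownames(x) <- NULL; x })()
}

#' Write a cohort panel to CSV
#' @param panel Cohort panel data.frame.
#' @param path Output file path.
#' @export
write_cohort_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input Path to a cohort CSV, or NULL to simulate from `sim`.
#' @param sim A [sim_config()] used when `input` is NULL.
#' @param raw_input Optional path/raw_feature_table for the QC stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("qc", "network", "panel", "lcmm", "pvar")` in pipeline order.
#' @param out_dir Output directory.
#' @param seed Integer seed for stage-level randomness.
#' @param qc_thresholds,beta,min_size,cut_height,k_range,alpha,
#'   pvar_transform,pvar_system,pvar_lags Stage parameters.
#' @param lcmm_response Growth score modelled by the latent-class stage.
#' @param n_restarts Restarts for the latent-class EM.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(),
                            raw_input = NULL,
                            stages = c("network", "panel", "lcmm", "pvar"),
                            out_dir = tempfile("glipnet_run_"),
                            seed = 1L,
                            qc_thresholds = glipnet::qc_thresholds(),
                            beta = 18, min_size = 10L, cut_height = 0.99,
                            k_range = 2:4, lcmm_response = "laz",
                            n_restarts = 3L,
                            alpha = 0.05, pvar_transform = "fod",
                            pvar_system = TRUE, pvar_lags = NULL) {
  known <- c("qc", "network", "panel", "lcmm", "pvar")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(input) && !file.exists(input)) {
    stop("input file does not exist: ", input)
  }
  structure(list(input = input, sim = sim, raw_input = raw_input,
                 stages = known[known %in% stages], out_dir = out_dir,
                 seed = as.integer(seed), qc_thresholds = qc_thresholds,
                 beta = beta, min_size = min_size, cut_height = cut_height,
                 k_range = k_range, lcmm_response = lcmm_response,
                 n_restarts = n_restarts, alpha = alpha,
                 pvar_transform = pvar_transform,
                 pvar_system = pvar_system, pvar_lags = pvar_lags),
            class = "pipeline_config")
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in order -- feature QC, signed correlation
#' network + eigenlipids, fixed-effects panel models + trend screen +
#' consecutive paired t-tests, latent-class growth trajectories, and the
#' system GMM panel VAR with temporal-network extraction -- each stage
#' consuming the previous stage's outputs, and writes every artifact plus
#' a run manifest to `config$out_dir`. Fully deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  files <- character(0)
  counts <- list()
  emit_csv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
    path
  }
  emit_json <- function(x, name) {
    write_json_out(x, file.path(config$out_dir, name))
    files <<- c(files, name)
  }
  fail_stage <- function(stage, e) {
    manifest <- list(failed_stage = stage, error = conditionMessage(e),
                     files = files)
    write_json_out(manifest, file.path(config$out_dir, "manifest.json"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # --- input ---
  if (is.null(config$input)) {
    simd <- simulate_study(config$sim)
    panel <- simd$panel
    emit_csv(panel, "cohort_panel.csv")
    emit_json(list(class_labels = simd$truth$class_labels,
                   module_assignment = as.list(simd$truth$module_assignment)),
              "ground_truth.json")
  } else {
    panel <- read_cohort_csv(config$input)
  }
  counts$panel_rows <- nrow(panel)
  counts$n_children <- length(unique(panel$child_id))
  feature_cols <- grep("^lipid_", names(panel), value = TRUE)

  # --- QC stage (raw feature table) ---
  if ("qc" %in% config$stages && !is.null(config$raw_input)) {
    tryCatch({
      raw <- if (inherits(config$raw_input, "raw_feature_table")) {
        config$raw_input
      } else stop("raw_input must be a raw_feature_table")
      qc <- apply_qc_filters(raw, config$qc_thresholds)
      emit_csv(qc$report, "qc_report.csv")
      emit_csv(qc$attrition, "qc_attrition.csv")
      emit_json(list(thresholds = config$qc_thresholds,
                     survivors = nrow(qc$filtered$intensities)),
                "qc_summary.json")
      counts$qc_survivors <- nrow(qc$filtered$intensities)
    }, error = function(e) fail_stage("qc", e))
  }

  me <- NULL
  if ("network" %in% config$stages) {
    tryCatch({
      x <- scale(as.matrix(panel[, feature_cols, drop = FALSE]))
      adj <- signed_adjacency(x, beta = config$beta)
      part <- detect_modules(topological_overlap(adj),
                             min_size = config$min_size,
                             cut_height = config$cut_height)
      me <- module_eigenlipids(x, part)
      emit_csv(data.frame(lipid = names(part$assignment),
                          module = part$assignment), "module_partition.csv")
      memat <- cbind(panel[, c("child_id", "visit_index")],
                     as.data.frame(me$values))
      emit_csv(memat, "eigenlipids.csv")
      net <- module_network(me)
      emit_csv(net$edges, "module_network_edges.csv")
      emit_json(list(r_squared = scale_free_fit(adj),
                     beta = config$beta,
                     n_modules = sum(me$modules > 0),
                     variance_explained = as.list(me$variance_explained)),
                "network_summary.json")
      counts$n_modules <- sum(me$modules > 0)
    }, error = function(e) fail_stage("network", e))
  }

  if ("panel" %in% config$stages) {
    tryCatch({
      fits <- lapply(c("waz", "laz", "wlz"), function(v) {
        f <- within_fe_fit(panel, v, "visit_index")
        cbind(response = v, f$coefficients)
      })
      emit_csv(do.call(rbind, fits), "growth_trends.csv")
      if (length(feature_cols)) {
        emit_csv(trend_screen(panel, feature_cols, alpha = config$alpha),
                 "lipid_trend_screen.csv")
      }
      if (!is.null(me)) {
        emit_csv(consecutive_paired_ttests(me$values, panel$child_id,
                                           panel$visit_index),
                 "eigenlipid_paired_ttests.csv")
        medf <- cbind(panel, as.data.frame(me$values))
        assoc <- lapply(colnames(me$values), function(q) {
          do.call(rbind, lapply(c("waz", "laz", "wlz"), function(v) {
            f <- within_fe_fit(medf, v, c("visit_index", q))
            cf <- f$coefficients[f$coefficients$term == q, , drop = FALSE]
            cbind(response = v, module = q, cf)
          }))
        })
        assoc <- do.call(rbind, assoc)
        assoc$fdr_p <- stats::ave(assoc$p_value, assoc$response,
                                  FUN = bh_fdr)
        emit_csv(assoc, "module_growth_associations.csv")
      }
    }, error = function(e) fail_stage("panel", e))
  }

  if ("lcmm" %in% config$stages) {
    tryCatch({
      sel <- select_num_classes(panel, config$lcmm_response,
                                k_range = config$k_range,
                                n_restarts = config$n_restarts,
                                seed = config$seed)
      emit_csv(sel$criteria, "lcmm_criteria.csv")
      post <- data.frame(child_id = sel$best$children,
                         class = sel$best$class_modal)
      post <- cbind(post, as.data.frame(sel$best$posterior))
      emit_csv(post, "lcmm_posterior.csv")
      emit_json(list(response = config$lcmm_response, K = sel$best$K,
                     pi = sel$best$pi, AIC = sel$best$AIC,
                     BIC = sel$best$BIC, loglik = sel$best$loglik,
                     converged = sel$best$converged),
                "lcmm_summary.json")
      counts$lcmm_K <- sel$best$K
    }, error = function(e) fail_stage("lcmm", e))
  }

  if ("pvar" %in% config$stages) {
    tryCatch({
      endo <- c("waz", "laz", "wlz",
                if (!is.null(me)) colnames(me$values) else character(0))
      pdat <- panel[, c("child_id", "visit_index", "sex", "waz", "laz",
                        "wlz")]
      if (!is.null(me)) pdat <- cbind(pdat, as.data.frame(me$values))
      spec <- pvar_spec(endo, lags = 1L, exogenous = "sex",
                        transform = config$pvar_transform,
                        system = config$pvar_system)
      if (!is.null(config$pvar_lags)) {
        lag_sel <- mmsc_lag_select(pdat, spec,
                                   p_candidates = config$pvar_lags)
        spec$lags <- lag_sel$p
        emit_csv(lag_sel$criteria, "pvar_lag_selection.csv")
      }
      model <- fit_pvar(pdat, spec, scale = TRUE)
      emit_json(list(
        endogenous = endo, lags = spec$lags,
        A = lapply(model$A, function(a) as.data.frame(a)),
        hansen = model$hansen[c("J", "df", "p")],
        eigen_moduli = model$eigen_moduli, stable = model$stable),
        "pvar_model.json")
      net <- extract_temporal_network(model, alpha = config$alpha)
      emit_csv(net$edges, "temporal_network_edges.csv")
      emit_json(list(nodes = net$nodes, alpha = net$alpha,
                     edges = net$edges), "temporal_network.json")
      counts$pvar_edges <- nrow(net$edges)
      counts$pvar_stable <- model$stable
    }, error = function(e) fail_stage("pvar", e))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("glipnet")),
    config_hash = rlang::hash(config),
    seed = config$seed,
    stages = config$stages,
    counts = counts,
    files = files,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  write_json_out(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
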