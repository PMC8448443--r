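#' Construct a raw lipid feature table
#'
#' Container for a feature-by-sample intensity matrix plus the metadata the
#' quality filters need: expected and mean observed mass per feature, and a
#' role (`study`, `blank` or `qc_dilution`) plus dilution factor per sample.
#'
#' @param intensities Nonnegative numeric matrix, features x samples.
#' @param feature_meta data.frame with columns `feature`, `expected_mass`,
#'   `observed_mass` (Daltons), one row per feature.
#' @param sample_meta data.frame with columns `sample`,
#'   `role` in study/blank/qc_dilution, and `dilution_factor` (required,
#'   positive, for every qc_dilution sample).
#' @return An object of class `raw_feature_table`.
#' @export
raw_feature_table <- function(intensities, feature_meta, sample_meta) {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == nrow(feature_meta),
            ncol(intensities) == nrow(sample_meta))
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative")
  }
  if (!all(c("feature", "expected_mass", "observed_mass") %in%
           names(feature_meta))) {
    stop("feature_meta needs columns feature, expected_mass, observed_mass")
  }
  if (!all(c("sample", "role") %in% names(sample_meta))) {
    stop("sample_meta needs columns sample, role")
  }
  bad_role <- setdiff(unique(sample_meta$role),
                      c("study", "blank", "qc_dilution"))
  if (length(bad_role)) stop("unknown sample role(s): ",
                             paste(bad_role, collapse = ", "))
  if (!any(sample_meta$role == "study")) stop("need >= 1 study sample")
  qc <- sample_meta$role == "qc_dilution"
  if (any(qc)) {
    if (is.null(sample_meta$dilution_factor) ||
        any(!is.finite(sample_meta$dilution_factor[qc])) ||
        any(sample_meta$dilution_factor[qc] <= 0)) {
      stop("every qc_dilution sample needs a positive dilution_factor")
    }
  }
  rownames(intensities) <- feature_meta$feature
  colnames(intensities) <- sample_meta$sample
  structure(list(intensities = intensities,
                 feature_meta = feature_meta,
                 sample_meta = sample_meta),
            class = "raw_feature_table")
}

#' @export
print.raw_feature_table <- function(x, ...) {
  cat("raw_feature_table:", nrow(x$intensities), "features x",
      ncol(x$intensities), "samples (",
      sum(x$sample_meta$role == "study"), "study,",
      sum(x$sample_meta$role == "blank"), "blank,",
      sum(x$sample_meta$role == "qc_dilution"), "dilution )\n")
  invisible(x)
}

#' Per-feature quality-control metrics
#'
#' Computes the four filter metrics for every feature:
#' \itemize{
#'   \item `ppm_deviation`: |mean observed mass - expected| / expected x 1e6;
#'   \item `blank_ratio`: mean study intensity / mean blank intensity
#'     (`Inf` when blanks are all zero, `NA` when there are no blanks);
#'   \item `zero_fraction`: share of study samples with intensity exactly 0;
#'   \item `dilution_r`: Pearson correlation of intensity with the dilution
#'     factor across qc_dilution samples (`NA` with fewer than 3 points, or
#'     when the feature's QC intensities are constant).
#' }
#' `NA` metrics mark a filter as not evaluable for that feature; such
#' features pass that filter by default (logged as a message).
#'
#' @param raw A [raw_feature_table()].
#' @param log_dilution Correlate against `log` intensities instead of raw
#'   intensities in the dilution series (default FALSE).
#' @return data.frame of class `qc_metrics`, one row per feature.
#' @export
compute_qc_metrics <- function(raw, log_dilution = FALSE) {
  stopifnot(inherits(raw, "raw_feature_table"))
  x <- raw$intensities
  study <- raw$sample_meta$role == "study"
  blank <- raw$sample_meta$role == "blank"
  qc <- raw$sample_meta$role == "qc_dilution"

  ppm <- abs(raw$feature_meta$observed_mass - raw$feature_meta$expected_mass) /
    raw$feature_meta$expected_mass * 1e6

  study_mean <- rowMeans(x[, study, drop = FALSE])
  if (any(blank)) {
    blank_mean <- rowMeans(x[, blank, drop = FALSE])
    blank_ratio <- ifelse(blank_mean == 0, Inf, study_mean / blank_mean)
  } else {
    message("no blank samples: blank-ratio filter not evaluable")
    blank_ratio <- rep(NA_real_, nrow(x))
  }

  zero_fraction <- rowMeans(x[, study, drop = FALSE] == 0)

  if (sum(qc) >= 3L) {
    dil <- raw$sample_meta$dilution_factor[qc]
    xin <- x[, qc, drop = FALSE]
    if (log_dilution) xin <- log1p(xin)
    dilution_r <- suppressWarnings(
      apply(xin, 1L, function(v) {
        if (stats::sd(v) == 0) NA_real_ else stats::cor(v, dil)
      })
    )
  } else {
    message("fewer than 3 dilution points: dilution filter not evaluable")
    dilution_r <- rep(NA_real_, nrow(x))
  }

  out <- data.frame(
    feature = raw$feature_meta$feature,
    ppm_deviation = ppm,
    blank_ratio = blank_ratio,
    zero_fraction = zero_fraction,
    dilution_r = dilution_r
  )
  class(out) <- c("qc_metrics", class(out))
  out
}

#' Default quality-filter thresholds
#' @export
qc_thresholds <- function(ppm = 5, blank_ratio = 5, zero_fraction = 0.10,
                          dilution_r = 0.9) {
  th <- list(ppm = ppm, blank_ratio = blank_ratio,
             zero_fraction = zero_fraction, dilution_r = dilution_r)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  th
}

#' Apply the four feature quality filters
#'
#' Removes features failing any of the four rules, each read with a strict
#' inequality at the printed threshold: mean mass deviation greater than
#' `ppm` parts per million; mean study intensity less than `blank_ratio`
#' times the mean blank intensity; intensity zero in more than
#' `zero_fraction` of study samples; dilution-series Pearson `r` below
#' `dilution_r`. The survivor set is the conjunction of the four rules
#' (order-invariant), but removals are attributed sequentially in the order
#' ppm, blank ratio, zero fraction, dilution so a per-step attrition table
#' can be reported.
#'
#' @param raw A [raw_feature_table()].
#' @param thresholds List as produced by [qc_thresholds()].
#' @param log_dilution Passed to [compute_qc_metrics()].
#' @return List with `filtered` (a `raw_feature_table` of survivors),
#'   `report` (per-feature metrics, pass flags, removal attribution) and
#'   `attrition` (features removed at each sequential step).
#' @export
apply_qc_filters <- function(raw, thresholds = qc_thresholds(),
                             log_dilution = FALSE) {
  metrics <- compute_qc_metrics(raw, log_dilution = log_dilution)
  pass_na <- function(flag) ifelse(is.na(flag), TRUE, flag)
  p_ppm <- pass_na(metrics$ppm_deviation <= thresholds$ppm)
  p_blank <- pass_na(metrics$blank_ratio >= thresholds$blank_ratio)
  p_zero <- pass_na(metrics$zero_fraction <= thresholds$zero_fraction)
  p_dil <- pass_na(metrics$dilution_r >= thresholds$dilution_r)

  overall <- p_ppm & p_blank & p_zero & p_dil
  removed_at <- rep(NA_character_, nrow(metrics))
  removed_at[!p_dil] <- "dilution_r"
  removed_at[!p_zero] <- "zero_fraction"
  removed_at[!p_blank] <- "blank_ratio"
  removed_at[!p_ppm] <- "ppm"          # earliest step wins

  report <- cbind(metrics,
                  data.frame(pass_ppm = p_ppm, pass_blank_ratio = p_blank,
                             pass_zero_fraction = p_zero,
                             pass_dilution_r = p_dil,
                             pass_overall = overall,
                             removed_at = removed_at))
  attr(report, "thresholds") <- thresholds
  class(report) <- c("filter_report", "data.frame")

  steps <- c("ppm", "blank_ratio", "zero_fraction", "dilution_r")
  attrition <- data.frame(
    step = steps,
    removed = vapply(steps, function(s) sum(removed_at == s, na.rm = TRUE),
                     integer(1))
  )
  attrition$remaining <- nrow(metrics) - cumsum(attrition$removed)

  if (!any(overall)) warning("no features survive the quality filters")
  filtered <- raw
  filtered$intensities <- raw$intensities[overall, , drop = FALSE]
  filtered$feature_meta <- raw$feature_meta[overall, , drop = FALSE]
  rownames(filtered$feature_meta) <- NULL

  list(filtered = filtered, report = report, attrition = attrition)
}
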