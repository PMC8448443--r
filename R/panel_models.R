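#' Fixed-effects (within) panel regression
#'
#' Estimates `response ~ covariates` with a child-specific intercept by
#' within-child demeaning: both sides are demeaned within child and the
#' slope coefficients are obtained by OLS on the demeaned data, which is
#' numerically identical to least-squares with a full set of child dummies.
#' Standard errors are clustered by child with the small-sample factor
#' G/(G-1) x (N-1)/(N-K), where G is the number of children, N the number
#' of observations and K the total parameter count (slopes plus child
#' intercepts).
#'
#' @param panel Long data.frame with a `child_id` column.
#' @param response Name of the response column.
#' @param covariates Character vector of time-varying covariate names;
#'   time-invariant columns (e.g. sex) are rejected with an explicit error
#'   because they are absorbed by the child fixed effect.
#' @param df_method `"normal"` (default) for z-based p-values, `"t"` for a
#'   t reference with G - 1 degrees of freedom.
#' @return Object of class `panel_fit`: a coefficient table with estimate,
#'   cluster-robust SE, statistic and p-value, plus `n_obs` and
#'   `n_children`.
#' @export
within_fe_fit <- function(panel, response, covariates,
                          df_method = c("normal", "t")) {
  df_method <- match.arg(df_method)
  cols <- c("child_id", response, covariates)
  miss <- setdiff(cols, names(panel))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- panel[stats::complete.cases(panel[, cols, drop = FALSE]),
             cols, drop = FALSE]
  id <- factor(d$child_id)
  if (nlevels(id) < 2L || nrow(d) < 4L) {
    stop("need >= 2 observations for >= 2 children")
  }
  x <- as.matrix(d[, covariates, drop = FALSE])
  for (j in seq_along(covariates)) {
    wvar <- tapply(x[, j], id, stats::var)
    if (all(wvar[!is.na(wvar)] < 1e-12)) {
      stop("covariate '", covariates[j],
           "' is time-invariant within children and cannot be estimated ",
           "by the within (fixed-effects) estimator")
    }
  }
  y <- d[[response]]
  demean <- function(v) v - ave(v, id)
  yd <- demean(y)
  xd <- apply(x, 2L, demean)
  if (!is.matrix(xd)) xd <- matrix(xd, ncol = length(covariates))
  colnames(xd) <- covariates

  xtx <- crossprod(xd)
  beta <- solve(xtx, crossprod(xd, yd))
  u <- yd - xd %*% beta

  g <- nlevels(id)
  n <- nrow(d)
  k <- length(covariates) + g  # slopes + absorbed child intercepts
  scores <- rowsum(xd * as.vector(u), id)
  meat <- crossprod(scores)
  bread <- solve(xtx)
  adj <- (g / (g - 1)) * ((n - 1) / (n - k))
  vcv <- adj * bread %*% meat %*% bread
  se <- sqrt(diag(vcv))
  stat <- as.vector(beta) / se
  p <- if (df_method == "normal") {
    2 * stats::pnorm(-abs(stat))
  } else {
    2 * stats::pt(-abs(stat), df = g - 1L)
  }
  out <- data.frame(term = covariates, estimate = as.vector(beta),
                    std_error = se, statistic = stat, p_value = p)
  structure(list(coefficients = out, vcov = vcv, n_obs = n, n_children = g,
                 response = response, df_method = df_method),
            class = "panel_fit")
}

#' @export
print.panel_fit <- function(x, ...) {
  cat("within fixed-effects fit:", x$response, "(", x$n_obs, "obs,",
      x$n_children, "children )\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: p_(i) is multiplied by m/i, a running minimum
#' is taken from the largest p downwards, and values are capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1] (NA allowed, passed
#'   through).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out
}

#' Screen features for time trends with FDR control
#'
#' Fits a within fixed-effects regression of each feature on the visit
#' index, adjusts the trend p-values across features by Benjamini-Hochberg,
#' and classifies each feature as `up`, `down` (FDR p below `alpha`, by
#' slope sign) or `flat`.
#'
#' @param panel Long data.frame with `child_id` and `time_var` columns.
#' @param features Character vector of feature column names.
#' @param alpha FDR level (default 0.05).
#' @param time_var Time covariate (default `visit_index`).
#' @return data.frame of class `trend_classification`: feature, slope,
#'   p_value, fdr_p, label.
#' @export
trend_screen <- function(panel, features, alpha = 0.05,
                         time_var = "visit_index") {
  res <- lapply(features, function(f) {
    ok <- !is.na(panel[[f]])
    if (!any(ok)) return(NULL)
    fit <- within_fe_fit(panel, f, time_var)
    data.frame(feature = f, slope = fit$coefficients$estimate[1L],
               p_value = fit$coefficients$p_value[1L])
  })
  dropped <- features[vapply(res, is.null, logical(1))]
  if (length(dropped)) {
    warning("dropped all-missing feature(s): ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, res)
  out$fdr_p <- bh_fdr(out$p_value)
  out$label <- ifelse(out$fdr_p < alpha,
                      ifelse(out$slope > 0, "up", "down"), "flat")
  class(out) <- c("trend_classification", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Share of children below a z-score cutoff, by latent class
#'
#' Cross-sectional prevalence of a growth deficit (stunting LAZ < -2,
#' wasting WLZ < -2, underweight WAZ < -2) at one visit week, overall or
#' within latent growth classes.
#'
#' @param panel Long cohort data.frame with `child_id`, `week` and the
#'   measure column.
#' @param week Visit week at which to evaluate.
#' @param measure Column name (default `"laz"`, i.e. stunting).
#' @param cutoff Threshold (default -2).
#' @param class_labels Optional named or child-ordered vector of class
#'   labels; when given, shares are reported per class.
#' @return data.frame: class (or "all"), n, n_below, share_pct.
#' @export
stunting_share <- function(panel, week, measure = "laz", cutoff = -2,
                           class_labels = NULL) {
  d <- panel[panel$week == week & !is.na(panel[[measure]]), , drop = FALSE]
  if (!nrow(d)) stop("no observations at week ", week)
  cls <- if (is.null(class_labels)) {
    rep("all", nrow(d))
  } else if (!is.null(names(class_labels))) {
    unname(class_labels[as.character(d$child_id)])
  } else {
    class_labels[match(d$child_id, sort(unique(panel$child_id)))]
  }
  agg <- tapply(d[[measure]] < cutoff, cls, function(v) {
    c(n = length(v), n_below = sum(v))
  })
  out <- do.call(rbind, lapply(names(agg), function(g) {
    data.frame(class = g, n = agg[[g]]["n"], n_below = agg[[g]]["n_below"])
  }))
  out$share_pct <- 100 * out$n_below / out$n
  rownames(out) <- NULL
  out
}

#' Paired t-tests between consecutive visits
#'
#' For each eigenlipid (or any feature column) and each consecutive visit
#' pair, a paired t-test restricted to children observed at both visits.
#' Significance tiers mirror the usual star convention: `*` p < 0.01,
#' `**` p < 0.001, `***` p < 0.0001.
#'
#' @param values Numeric matrix (observations x features), e.g.
#'   `me$values`, or a data.frame of feature columns.
#' @param child_id,visit_index Vectors aligned with the rows of `values`.
#' @return data.frame: feature, visit_from, visit_to, n_pairs, mean_diff,
#'   t, df, p_value, tier.
#' @export
consecutive_paired_ttests <- function(values, child_id, visit_index) {
  v <- as.matrix(values)
  stopifnot(length(child_id) == nrow(v), length(visit_index) == nrow(v))
  visits <- sort(unique(visit_index))
  feats <- colnames(v)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(v)))
  rows <- list()
  for (f in seq_len(ncol(v))) {
    for (i in seq_len(length(visits) - 1L)) {
      v1 <- visits[i]; v2 <- visits[i + 1L]
      a <- v[visit_index == v1, f][match(
        intersect(child_id[visit_index == v1], child_id[visit_index == v2]),
        child_id[visit_index == v1])]
      b <- v[visit_index == v2, f][match(
        intersect(child_id[visit_index == v1], child_id[visit_index == v2]),
        child_id[visit_index == v2])]
      ok <- !is.na(a) & !is.na(b)
      a <- a[ok]; b <- b[ok]
      if (length(a) < 2L) {
        warning("fewer than 2 complete pairs for ", feats[f], " at visits ",
                v1, "-", v2, "; pair skipped")
        next
      }
      dif <- b - a
      if (stats::sd(dif) == 0) {
        tstat <- 0; pval <- 1; dfree <- length(dif) - 1L
      } else {
        tt <- stats::t.test(b, a, paired = TRUE)
        tstat <- unname(tt$statistic); pval <- tt$p.value
        dfree <- unname(tt$parameter)
      }
      tier <- if (pval < 1e-4) "***" else if (pval < 1e-3) "**" else
        if (pval < 1e-2) "*" else ""
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feats[f], visit_from = v1, visit_to = v2,
        n_pairs = length(dif), mean_diff = mean(dif), t = tstat,
        df = dfree, p_value = pval, tier = tier)
    }
  }
  do.call(rbind, rows)
}
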