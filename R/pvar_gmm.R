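#' Specification of a panel vector autoregression
#'
#' @param endogenous Character vector of endogenous variable names (k >= 1).
#' @param lags Lag order p (>= 1).
#' @param exogenous Character vector of exogenous regressors (e.g. `"sex"`);
#'   time-invariant exogenous variables enter the levels equation only,
#'   because the first-difference / forward-orthogonal-deviation transform
#'   annihilates them.
#' @param transform `"fod"` (forward orthogonal deviations, default) or
#'   `"fd"` (first differences) for the transformed equation.
#' @param system Include the levels equation instrumented by lagged
#'   differences (system GMM, default TRUE) or estimate the transformed
#'   equation alone (difference GMM).
#' @param depth Maximum instrument lag depth (default `Inf` = full
#'   available history).
#' @param collapse Collapse period-specific instrument blocks into one
#'   column per lag distance (default FALSE).
#' @param steps `"twostep"` (default) or `"onestep"` GMM.
#' @return Object of class `pvar_spec`.
#' @export
pvar_spec <- function(endogenous, lags = 1L, exogenous = character(),
                      transform = c("fod", "fd"), system = TRUE,
                      depth = Inf, collapse = FALSE,
                      steps = c("twostep", "onestep")) {
  transform <- match.arg(transform)
  steps <- match.arg(steps)
  stopifnot(length(endogenous) >= 1L, lags >= 1L, depth >= 2L)
  structure(list(endogenous = endogenous, lags = as.integer(lags),
                 exogenous = exogenous, transform = transform,
                 system = isTRUE(system), depth = depth,
                 collapse = isTRUE(collapse), steps = steps),
            class = "pvar_spec")
}

#' Forward orthogonal deviations of one time series
#'
#' x*_t = sqrt(m_t / (m_t + 1)) * (x_t - mean of the m_t available future
#' observations). The last available observation (no future values) maps to
#' NA; gaps are handled by averaging over available future observations
#' only. The transform removes any per-child constant exactly.
#'
#' @param x Numeric vector ordered in time; NA marks a missing period.
#' @return Numeric vector of the same length.
#' @export
fod_transform <- function(x) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (is.na(x[t])) next
    fut <- x[seq_len(n) > t]
    fut <- fut[!is.na(fut)]
    m <- length(fut)
    if (m == 0L) next
    out[t] <- sqrt(m / (m + 1)) * (x[t] - mean(fut))
  }
  out
}

# panel -> array Y[N, T, k]; requires child_id and visit_index columns
panel_array <- function(panel, vars) {
  miss <- setdiff(c("child_id", "visit_index", vars), names(panel))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ids <- sort(unique(panel$child_id))
  tt <- max(panel$visit_index)
  y <- array(NA_real_, c(length(ids), tt, length(vars)),
             dimnames = list(NULL, NULL, vars))
  ri <- match(panel$child_id, ids)
  ci <- panel$visit_index
  for (j in seq_along(vars)) {
    y[cbind(ri, ci, j)] <- panel[[vars[j]]]
  }
  list(y = y, ids = ids, tt = tt)
}

apply_fod_array <- function(y) {
  out <- y
  for (i in seq_len(dim(y)[1])) {
    for (j in seq_len(dim(y)[3])) out[i, , j] <- fod_transform(y[i, , j])
  }
  out
}

#' Build the stacked GMM moment system for a PVAR
#'
#' Constructs, per equation period, the transformed dependent variables and
#' regressors together with the instrument matrix: period-specific blocks
#' of lagged levels of all endogenous variables for the transformed
#' equation (levels dated t-2 and earlier under first differencing, t-1 and
#' earlier under forward orthogonal deviations), and, when `spec$system`,
#' a levels equation instrumented by the lagged first difference of each
#' endogenous variable, with exogenous variables instrumenting themselves.
#' Missing instrument entries are zero-filled; rows are retained whenever
#' the dependent variable and all regressors are observed, so unbalanced
#' panels are supported. `spec$collapse` sums instrument blocks across
#' periods into one column per lag distance.
#'
#' @param panel Long data.frame sorted by child and visit, with `child_id`
#'   and `visit_index` columns.
#' @param spec A [pvar_spec()].
#' @return List with `X` (regressors), `Y` (dependent matrix, one column
#'   per equation), `Z` (instruments), `child`, `period`, `type`
#'   (fd/fod/levels per row), `coef_names`, and bookkeeping counts.
#' @export
build_gmm_system <- function(panel, spec) {
  stopifnot(inherits(spec, "pvar_spec"))
  pa <- panel_array(panel, c(spec$endogenous, spec$exogenous))
  k <- length(spec$endogenous)
  p <- spec$lags
  y <- pa$y[, , spec$endogenous, drop = FALSE]
  tt <- pa$tt
  n <- dim(y)[1]
  if (tt < p + 2L) {
    stop("need at least ", p + 2L, " periods for a lag-", p,
         " GMM system (have ", tt, ")")
  }
  lag_arr <- function(l) {
    out <- array(NA_real_, dim(y))
    out[, (l + 1L):tt, ] <- y[, 1:(tt - l), , drop = FALSE]
    out
  }
  lags <- lapply(seq_len(p), lag_arr)

  if (spec$transform == "fd") {
    dstar <- y - lag_arr(1L)
    xstar <- lapply(lags, function(a) {
      s <- array(NA_real_, dim(y))
      s[, 2:tt, ] <- a[, 2:tt, , drop = FALSE] - a[, 1:(tt - 1L), , drop = FALSE]
      s
    })
    inst_from <- 2L   # instruments dated t-2 and earlier
    t_rows <- seq.int(p + 2L, tt)
  } else {
    dstar <- apply_fod_array(y)
    xstar <- lapply(lags, apply_fod_array)
    inst_from <- 1L   # fod error at t involves shocks t..T: t-1 is valid
    t_rows <- seq.int(p + 1L, tt)
  }

  coef_names <- c(
    unlist(lapply(seq_len(p), function(l) {
      paste0("lag", l, "_", spec$endogenous)
    })),
    spec$exogenous
  )
  b <- k * p + length(spec$exogenous)

  rows_x <- list(); rows_y <- list(); rows_child <- list()
  rows_t <- list(); rows_type <- list(); z_trans <- list()

  depth <- spec$depth
  zero_na <- function(m) { m[is.na(m)] <- 0; m }

  # ---- transformed-equation rows ----
  trans_cols <- list()  # per period t, the instrument design
  for (t in t_rows) {
    dep <- dstar[, t, , drop = TRUE]
    if (k == 1L) dep <- matrix(dep, ncol = 1L)
    reg <- do.call(cbind, lapply(xstar, function(a) {
      m <- a[, t, , drop = TRUE]
      if (k == 1L) m <- matrix(m, ncol = 1L) else m
    }))
    ok <- stats::complete.cases(cbind(dep, reg))
    if (!any(ok)) next
    s_hi <- t - inst_from
    s_lo <- max(1L, t - ifelse(is.finite(depth), depth, tt))
    if (s_hi < s_lo) next
    svals <- s_lo:s_hi
    zi <- do.call(cbind, lapply(svals, function(s) {
      m <- y[, s, , drop = TRUE]
      if (k == 1L) m <- matrix(m, ncol = 1L)
      colnames(m) <- paste0("L", t - s, "_", spec$endogenous,
                            if (!spec$collapse) paste0("_t", t) else "")
      zero_na(m)
    }))
    nr <- sum(ok)
    rows_x[[length(rows_x) + 1L]] <-
      cbind(reg[ok, , drop = FALSE],
            matrix(0, nr, length(spec$exogenous)))
    rows_y[[length(rows_y) + 1L]] <- dep[ok, , drop = FALSE]
    rows_child[[length(rows_child) + 1L]] <- which(ok)
    rows_t[[length(rows_t) + 1L]] <- rep(t, nr)
    rows_type[[length(rows_type) + 1L]] <- rep(spec$transform, nr)
    trans_cols[[length(trans_cols) + 1L]] <- zi[ok, , drop = FALSE]
  }
  if (!length(rows_x)) stop("no usable transformed-equation rows")

  # assemble transformed instruments: block per period, or collapsed
  if (spec$collapse) {
    all_names <- unique(unlist(lapply(trans_cols, colnames)))
    z_t <- lapply(trans_cols, function(m) {
      out <- matrix(0, nrow(m), length(all_names),
                    dimnames = list(NULL, all_names))
      out[, colnames(m)] <- m
      out
    })
    z_trans_mat <- do.call(rbind, z_t)
  } else {
    tot <- sum(vapply(trans_cols, ncol, integer(1)))
    offs <- cumsum(c(0L, vapply(trans_cols, ncol, integer(1))))
    nr_all <- vapply(trans_cols, nrow, integer(1))
    z_trans_mat <- matrix(0, sum(nr_all), tot)
    cn <- character(tot)
    at <- 0L
    for (i in seq_along(trans_cols)) {
      ridx <- at + seq_len(nr_all[i])
      cidx <- offs[i] + seq_len(ncol(trans_cols[[i]]))
      z_trans_mat[ridx, cidx] <- trans_cols[[i]]
      cn[cidx] <- colnames(trans_cols[[i]])
      at <- at + nr_all[i]
    }
    colnames(z_trans_mat) <- cn
  }

  # ---- levels-equation rows (system GMM) ----
  z_lev_mat <- NULL
  if (spec$system) {
    lev_cols <- list()
    dy1 <- array(NA_real_, dim(y))
    dy1[, 2:tt, ] <- y[, 2:tt, , drop = FALSE] - y[, 1:(tt - 1L), , drop = FALSE]
    exo <- if (length(spec$exogenous)) {
      pa$y[, , spec$exogenous, drop = FALSE]
    } else NULL
    for (t in seq.int(p + 1L, tt)) {
      dep <- y[, t, , drop = TRUE]
      if (k == 1L) dep <- matrix(dep, ncol = 1L)
      reg <- do.call(cbind, lapply(seq_len(p), function(l) {
        m <- lags[[l]][, t, , drop = TRUE]
        if (k == 1L) matrix(m, ncol = 1L) else m
      }))
      ex_reg <- if (length(spec$exogenous)) {
        m <- exo[, t, , drop = TRUE]
        if (length(spec$exogenous) == 1L) matrix(m, ncol = 1L) else m
      } else matrix(0, n, 0L)
      ok <- stats::complete.cases(cbind(dep, reg, ex_reg))
      if (!any(ok)) next
      # lagged difference of each endogenous variable as instrument
      zi <- dy1[, t - 1L, , drop = TRUE]
      if (k == 1L) zi <- matrix(zi, ncol = 1L)
      colnames(zi) <- paste0("D1_", spec$endogenous,
                             if (!spec$collapse) paste0("_t", t) else "")
      zi <- zero_na(zi)
      if (length(spec$exogenous)) {
        ze <- zero_na(ex_reg)
        colnames(ze) <- paste0("X_", spec$exogenous,
                               if (!spec$collapse) paste0("_t", t) else "")
        zi <- cbind(zi, ze)
      }
      nr <- sum(ok)
      rows_x[[length(rows_x) + 1L]] <-
        cbind(reg[ok, , drop = FALSE], ex_reg[ok, , drop = FALSE])
      rows_y[[length(rows_y) + 1L]] <- dep[ok, , drop = FALSE]
      rows_child[[length(rows_child) + 1L]] <- which(ok)
      rows_t[[length(rows_t) + 1L]] <- rep(t, nr)
      rows_type[[length(rows_type) + 1L]] <- rep("levels", nr)
      lev_cols[[length(lev_cols) + 1L]] <- zi[ok, , drop = FALSE]
    }
    if (spec$collapse) {
      all_names <- unique(unlist(lapply(lev_cols, colnames)))
      z_l <- lapply(lev_cols, function(m) {
        out <- matrix(0, nrow(m), length(all_names),
                      dimnames = list(NULL, all_names))
        out[, colnames(m)] <- m
        out
      })
      z_lev_mat <- do.call(rbind, z_l)
    } else {
      tot <- sum(vapply(lev_cols, ncol, integer(1)))
      offs <- cumsum(c(0L, vapply(lev_cols, ncol, integer(1))))
      nr_all <- vapply(lev_cols, nrow, integer(1))
      z_lev_mat <- matrix(0, sum(nr_all), tot)
      cn <- character(tot)
      at <- 0L
      for (i in seq_along(lev_cols)) {
        ridx <- at + seq_len(nr_all[i])
        cidx <- offs[i] + seq_len(ncol(lev_cols[[i]]))
        z_lev_mat[ridx, cidx] <- lev_cols[[i]]
        cn[cidx] <- colnames(lev_cols[[i]])
        at <- at + nr_all[i]
      }
      colnames(z_lev_mat) <- cn
    }
  }

  x <- do.call(rbind, rows_x)
  colnames(x) <- coef_names
  ymat <- do.call(rbind, rows_y)
  colnames(ymat) <- spec$endogenous
  child <- unlist(rows_child)
  period <- unlist(rows_t)
  type <- unlist(rows_type)

  n_tr <- nrow(z_trans_mat)
  n_lv <- if (is.null(z_lev_mat)) 0L else nrow(z_lev_mat)
  z <- matrix(0, n_tr + n_lv, ncol(z_trans_mat) +
                if (is.null(z_lev_mat)) 0L else ncol(z_lev_mat))
  z[seq_len(n_tr), seq_len(ncol(z_trans_mat))] <- z_trans_mat
  cn <- colnames(z_trans_mat)
  if (!is.null(z_lev_mat)) {
    z[n_tr + seq_len(n_lv), ncol(z_trans_mat) + seq_len(ncol(z_lev_mat))] <-
      z_lev_mat
    cn <- c(cn, colnames(z_lev_mat))
  }
  colnames(z) <- cn
  nonzero <- colSums(abs(z)) > 0  # e.g. lagged differences before period 3
  z <- z[, nonzero, drop = FALSE]

  list(X = x, Y = ymat, Z = z, child = child, period = period, type = type,
       coef_names = coef_names, spec = spec,
       n_children = length(unique(child)), n_obs = nrow(x),
       n_instruments = ncol(z), ids = pa$ids)
}

solve_safe <- function(m, label = "matrix") {
  out <- tryCatch(solve(m), error = function(e) NULL)
  if (is.null(out)) {
    warning(label, " is singular: ridge-regularized")
    out <- solve(m + diag(1e-8 * mean(diag(m)) + 1e-12, nrow(m)))
  }
  out
}

#' Fit a panel VAR by first-difference or system GMM
#'
#' One-step GMM uses a weighting matrix built from the instrument
#' cross-product (the first-difference H matrix on differenced rows,
#' identity blocks on forward-orthogonal-deviation and levels rows); the
#' two-step estimator re-weights each equation with the inverse clustered
#' moment covariance from the one-step residuals. Equations share the
#' regressor and instrument matrices and are estimated equation by
#' equation, which for this design coincides with joint estimation under
#' block-diagonal weighting. Standard errors are robust (sandwich for
#' one-step, inverse Fisher form for two-step, no small-sample
#' correction); p-values use the normal approximation.
#'
#' @param panel Long data.frame with `child_id`, `visit_index` and the
#'   variables named in `spec`.
#' @param spec A [pvar_spec()].
#' @param scale Z-standardize the endogenous variables before estimation so
#'   coefficients are comparable across variables (default FALSE; the
#'   pipeline enables it for network extraction).
#' @param windmeijer Apply the Windmeijer finite-sample correction to the
#'   two-step standard errors (default TRUE; without it two-step SEs are
#'   downward biased and edge tests overreject).
#' @return Object of class `pvar_model` with lag coefficient matrices
#'   `A` (list per lag, entry [q, j] = effect of variable j at lag l on
#'   equation q), exogenous coefficients, SEs and p-values, the Hansen J
#'   statistic, companion eigenvalues and a stability flag.
#' @export
fit_pvar <- function(panel, spec, scale = FALSE, windmeijer = TRUE) {
  if (scale) {
    for (v in spec$endogenous) {
      panel[[v]] <- as.numeric(base::scale(panel[[v]]))
    }
  }
  sys <- build_gmm_system(panel, spec)
  x <- sys$X; z <- sys$Z; ymat <- sys$Y
  k <- length(spec$endogenous)
  b <- ncol(x)
  m_inst <- ncol(z)
  if (m_inst > sys$n_children) {
    warning("instrument count (", m_inst, ") exceeds number of children (",
            sys$n_children, "): Hansen test may be weak")
  }

  # one-step weighting: H tridiagonal on fd rows, identity elsewhere
  zhz <- crossprod(z)
  fd_rows <- which(sys$type == "fd")
  if (length(fd_rows)) {
    zhz <- zhz + crossprod(z[fd_rows, , drop = FALSE])
    key <- paste(sys$child, sys$period, sys$type)
    nxt <- match(paste(sys$child, sys$period + 1L, sys$type), key)
    a_idx <- fd_rows[!is.na(nxt[fd_rows])]
    b_idx <- nxt[a_idx]
    if (length(a_idx)) {
      sub <- crossprod(z[a_idx, , drop = FALSE], z[b_idx, , drop = FALSE])
      zhz <- zhz - sub - t(sub)
    }
  }
  w1 <- solve_safe(zhz, "one-step weighting matrix")

  sx <- crossprod(z, x)          # M x b
  sy <- crossprod(z, ymat)       # M x k
  bread1 <- solve_safe(t(sx) %*% w1 %*% sx, "one-step GMM normal matrix")
  b1 <- bread1 %*% t(sx) %*% w1 %*% sy            # b x k
  u1 <- ymat - x %*% b1

  omega <- lapply(seq_len(k), function(q) {
    crossprod(rowsum(z * u1[, q], sys$child))
  })

  if (spec$steps == "twostep") {
    coefs <- matrix(0, b, k)
    vcovs <- vector("list", k)
    w2 <- lapply(omega, solve_safe, label = "two-step weighting matrix")
    px <- lapply(seq_len(b), function(j) rowsum(z * x[, j], sys$child))
    for (q in seq_len(k)) {
      fisher <- t(sx) %*% w2[[q]] %*% sx
      vq <- solve_safe(fisher, "two-step GMM normal matrix")
      coefs[, q] <- vq %*% t(sx) %*% w2[[q]] %*% sy[, q]
      vcovs[[q]] <- vq
      if (windmeijer) {
        # finite-sample correction for the extra variability introduced by
        # the estimated weighting matrix (uncorrected two-step SEs are
        # downward biased and overreject)
        u2q <- ymat[, q] - x %*% coefs[, q]
        m2 <- crossprod(z, u2q)
        pu <- rowsum(z * u1[, q], sys$child)
        dmat <- matrix(0, b, b)
        for (j in seq_len(b)) {
          cj <- crossprod(px[[j]], pu)
          dmat[, j] <- vq %*% (t(sx) %*% (w2[[q]] %*%
                                            ((cj + t(cj)) %*%
                                               (w2[[q]] %*% m2))))
        }
        bread1 <- solve_safe(t(sx) %*% w1 %*% sx, "one-step normal matrix")
        v1r <- bread1 %*% (t(sx) %*% w1 %*% omega[[q]] %*% w1 %*% sx) %*%
          bread1
        vcovs[[q]] <- vq + dmat %*% vq + vq %*% t(dmat) +
          dmat %*% v1r %*% t(dmat)
      }
    }
    u2 <- ymat - x %*% coefs
    j_eq <- vapply(seq_len(k), function(q) {
      mq <- crossprod(z, u2[, q])
      as.numeric(t(mq) %*% w2[[q]] %*% mq)
    }, numeric(1))
  } else {
    coefs <- b1
    vcovs <- lapply(seq_len(k), function(q) {
      bread1 %*% (t(sx) %*% w1 %*% omega[[q]] %*% w1 %*% sx) %*% bread1
    })
    winv <- lapply(omega, solve_safe, label = "moment covariance")
    j_eq <- vapply(seq_len(k), function(q) {
      mq <- crossprod(z, u1[, q])
      as.numeric(t(mq) %*% winv[[q]] %*% mq)
    }, numeric(1))
  }

  se <- vapply(vcovs, function(v) sqrt(pmax(diag(v), 0)), numeric(b))
  se <- matrix(se, b, k)
  zstat <- coefs / se
  pval <- 2 * stats::pnorm(-abs(zstat))
  dimnames(coefs) <- dimnames(se) <- dimnames(zstat) <- dimnames(pval) <-
    list(sys$coef_names, spec$endogenous)

  p <- spec$lags
  a_list <- lapply(seq_len(p), function(l) {
    idx <- (l - 1L) * k + seq_len(k)
    t(coefs[idx, , drop = FALSE])  # [equation q, source j]
  })
  exog_coef <- if (length(spec$exogenous)) {
    t(coefs[k * p + seq_along(spec$exogenous), , drop = FALSE])
  } else NULL

  df_j <- k * (m_inst - b)
  j_total <- sum(j_eq)
  hansen <- list(J = if (df_j == 0L) 0 else j_total, df = df_j,
                 p = if (df_j > 0L) stats::pchisq(j_total, df_j,
                                                 lower.tail = FALSE)
                     else NA_real_,
                 just_identified = df_j == 0L, per_equation = j_eq)

  stab <- stability_check(a_list)
  structure(list(
    A = a_list, exog_coef = exog_coef, coefficients = coefs, se = se,
    z = zstat, p_values = pval, hansen = hansen,
    n_instruments = m_inst, n_moments = k * m_inst,
    n_parameters = k * b, n_children = sys$n_children, n_obs = sys$n_obs,
    companion = stab$companion, eigen_moduli = stab$moduli,
    stable = stab$stable, spec = spec, scaled = scale
  ), class = "pvar_model")
}

#' @export
print.pvar_model <- function(x, ...) {
  k <- length(x$spec$endogenous)
  cat("panel VAR(", x$spec$lags, "), ", k, " endogenous, ",
      x$spec$steps, " ", ifelse(x$spec$system, "system", "difference"),
      " GMM (", x$spec$transform, ")\n",
      "  children: ", x$n_children, "  rows: ", x$n_obs,
      "  instruments/eq: ", x$n_instruments, "\n",
      "  Hansen J = ", signif(x$hansen$J, 5), " (df ", x$hansen$df,
      ", p = ", signif(x$hansen$p, 3), ")  stable: ", x$stable, "\n",
      sep = "")
  invisible(x)
}

#' Hansen test of overidentifying restrictions
#'
#' J statistic aggregated over the equations, with degrees of freedom
#' equal to total moment conditions minus estimated coefficients. For a
#' just-identified system J is reported as 0 with an undefined p-value.
#'
#' @param model A fitted [fit_pvar()] model.
#' @return List with `J`, `df`, `p` and `just_identified`.
#' @export
hansen_j <- function(model) {
  stopifnot(inherits(model, "pvar_model"))
  model$hansen
}

#' Andrews-Lu moment selection over candidate lag orders
#'
#' Fits the PVAR for each candidate lag order and computes the moment- and
#' model-selection criteria MMSC_BIC = J - (c - b) ln N,
#' MMSC_AIC = J - 2 (c - b), and MMSC_HQIC = J - 2.1 (c - b) ln ln N,
#' where c is the number of moment conditions, b the number of estimated
#' parameters and N the number of children. The chosen order minimizes the
#' configured criterion, with ties broken toward the smaller lag.
#'
#' @param panel Long panel data.frame.
#' @param spec A [pvar_spec()] template (its `lags` field is overridden).
#' @param p_candidates Candidate lag orders (default `c(1, 2)`).
#' @param criterion `"BIC"` (default), `"AIC"` or `"HQIC"`.
#' @return List with `criteria` (one row per candidate) and `p` (chosen
#'   lag order).
#' @export
mmsc_lag_select <- function(panel, spec, p_candidates = c(1L, 2L),
                            criterion = c("BIC", "AIC", "HQIC")) {
  criterion <- match.arg(criterion)
  p_candidates <- sort(as.integer(p_candidates))
  rows <- lapply(p_candidates, function(pc) {
    sp <- spec
    sp$lags <- pc
    fit <- tryCatch(fit_pvar(panel, sp), error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(p = pc, feasible = FALSE, J = NA, c = NA, b = NA,
                        N = NA, MMSC_BIC = NA, MMSC_AIC = NA,
                        MMSC_HQIC = NA))
    }
    j <- fit$hansen$J
    cc <- fit$n_moments
    bb <- fit$n_parameters
    nn <- fit$n_children
    data.frame(p = pc, feasible = TRUE, J = j, c = cc, b = bb, N = nn,
               MMSC_BIC = j - (cc - bb) * log(nn),
               MMSC_AIC = j - 2 * (cc - bb),
               MMSC_HQIC = j - 2.1 * (cc - bb) * log(log(nn)))
  })
  criteria <- do.call(rbind, rows)
  col <- paste0("MMSC_", criterion)
  ok <- which(criteria$feasible)
  if (!length(ok)) stop("no feasible lag order among candidates")
  chosen <- criteria$p[ok[which.min(criteria[[col]][ok])]]
  list(criteria = criteria, p = chosen, criterion = criterion)
}

#' Companion-matrix stability analysis
#'
#' Builds the companion matrix of the lag polynomial, computes its complex
#' eigenvalues, and declares the model stable when every modulus is
#' strictly below 1 (all roots inside the unit circle).
#'
#' @param model A `pvar_model`, or a list of k x k lag coefficient
#'   matrices A_1..A_p.
#' @return List with `companion`, `eigenvalues` (complex), `moduli`,
#'   `stable`, and `unit_circle` (data.frame of Re/Im coordinates for
#'   plotting).
#' @export
stability_check <- function(model) {
  a_list <- if (inherits(model, "pvar_model")) model$A else model
  if (is.matrix(a_list)) a_list <- list(a_list)
  k <- nrow(a_list[[1L]])
  p <- length(a_list)
  comp <- matrix(0, k * p, k * p)
  comp[seq_len(k), ] <- do.call(cbind, a_list)
  if (p > 1L) {
    comp[k + seq_len(k * (p - 1L)), seq_len(k * (p - 1L))] <-
      diag(k * (p - 1L))
  }
  ev <- eigen(comp, only.values = TRUE)$values
  moduli <- Mod(ev)
  list(companion = comp, eigenvalues = ev, moduli = moduli,
       stable = all(moduli < 1),
       unit_circle = data.frame(re = Re(ev), im = Im(ev),
                                modulus = moduli))
}

#' Extract the signed directed temporal network
#'
#' One directed edge source -> target for every lag-1 coefficient with
#' p-value below `alpha`: the current value of the source variable
#' consistently predicts the next-period value of the target (a
#' Granger-type association). Edge weight is the coefficient; diagonal
#' entries give self-loops.
#'
#' @param model A fitted [fit_pvar()] model.
#' @param alpha Significance threshold (default 0.05).
#' @return Object of class `temporal_network`: `nodes`, `edges`
#'   (data.frame source, target, weight, sign, p_value) and `alpha`.
#' @export
extract_temporal_network <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "pvar_model"))
  vars <- model$spec$endogenous
  k <- length(vars)
  a1 <- model$A[[1L]]
  pv <- t(model$p_values[seq_len(k), , drop = FALSE])  # [equation, source]
  idx <- which(pv < alpha, arr.ind = TRUE)
  edges <- data.frame(
    source = vars[idx[, 2L]],
    target = vars[idx[, 1L]],
    weight = a1[idx],
    sign = ifelse(a1[idx] >= 0, "positive", "negative"),
    p_value = pv[idx]
  )
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = vars, edges = edges, alpha = alpha),
            class = "temporal_network")
}

#' @export
print.temporal_network <- function(x, ...) {
  cat("temporal network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges at alpha =", x$alpha, "\n")
  if (nrow(x$edges)) print(utils::head(x$edges, 20L), row.names = FALSE)
  invisible(x)
}
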