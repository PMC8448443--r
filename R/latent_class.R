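#' Natural cubic spline basis with knots at age quantiles
#'
#' Builds the trajectory basis used by the latent-class growth model: a
#' natural cubic spline with knots at `n_knots` quantiles of the observed
#' ages (boundary knots at the extreme quantiles, the rest interior), plus
#' an explicit intercept column. With the default five knots and the five
#' scheduled visit ages the basis has five columns and interpolates any
#' per-visit mean pattern exactly.
#'
#' @param age Numeric vector of observed ages (e.g. weeks).
#' @param n_knots Number of quantile knots (default 5).
#' @return Object of class `spline_basis`: `design` (rows aligned with
#'   `age`), `knots`, `boundary`, and a `predict` closure for new ages.
#' @export
quantile_spline_basis <- function(age, n_knots = 5L) {
  age <- as.numeric(age)
  ua <- sort(unique(age[!is.na(age)]))
  if (length(ua) < 2L) stop("age must take >= 2 distinct values")
  qs <- stats::quantile(age, probs = seq(0, 1, length.out = n_knots),
                        na.rm = TRUE, names = FALSE)
  qs <- unique(qs)
  if (length(qs) < n_knots) {
    warning("tied age quantiles collapsed: using ", length(qs), " knots")
  }
  if (length(qs) < 2L) stop("degenerate age distribution")
  boundary <- range(qs)
  interior <- qs[qs > boundary[1] & qs < boundary[2]]
  make <- function(a) {
    b <- splines::ns(a, knots = interior, Boundary.knots = boundary)
    cbind(`(Intercept)` = 1, b)
  }
  design <- make(age)
  if (qr(design[!is.na(age), , drop = FALSE])$rank < ncol(design)) {
    stop("spline basis is rank deficient on the observed ages")
  }
  structure(list(design = design, knots = interior, boundary = boundary,
                 predict = make),
            class = "spline_basis")
}

logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Latent-class linear mixed model of growth trajectories
#'
#' Fits a K-class mixture of linear mixed models by EM: each class has its
#' own mean trajectory over a natural cubic spline basis of age, all
#' classes share a random intercept-and-slope covariance and a residual
#' variance, and sex (when present) enters the trajectory mean additively
#' with a common coefficient. Children with incomplete visit schedules
#' contribute the marginal likelihood of their observed visits only.
#' The E-step computes posterior class probabilities from each child's
#' class-specific marginal Gaussian likelihood; the M-step performs exact
#' conditional maximizations (weighted least squares for the trajectories,
#' closed-form updates for the variance components), so the observed-data
#' log-likelihood is non-decreasing at every iteration (asserted).
#' The best of `n_restarts` random initializations is kept and classes are
#' relabelled by ascending fitted trajectory at the first visit.
#'
#' @param panel Long data.frame with columns `child_id`, `visit_index`,
#'   the response, an age column and optionally `sex`.
#' @param response Response column name (e.g. `"laz"`).
#' @param K Number of latent classes (>= 1).
#' @param n_restarts Random restarts (default 10).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations per restart (default 200).
#' @param seed Integer seed controlling the restarts.
#' @param age_var Column used for the spline basis (default `"week"`).
#' @param n_knots Quantile knots for the basis (default 5).
#' @param use_sex Include an additive sex term when a `sex` column exists
#'   (default TRUE).
#' @return Object of class `latent_class_model`.
#' @export
fit_latent_class_mixed <- function(panel, response, K,
                                   n_restarts = 10L, tol = 1e-6,
                                   max_iter = 200L, seed = 1L,
                                   age_var = "week", n_knots = 5L,
                                   use_sex = TRUE) {
  stopifnot(K >= 1L)
  need <- c("child_id", "visit_index", response, age_var)
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- panel[!is.na(panel[[response]]), , drop = FALSE]
  ids <- sort(unique(d$child_id))
  n <- length(ids)
  visits <- sort(unique(d$visit_index))
  tt <- length(visits)
  # per-visit age (schedule shared across children)
  age_of <- vapply(visits, function(v) {
    stats::median(d[[age_var]][d$visit_index == v], na.rm = TRUE)
  }, numeric(1))
  basis <- quantile_spline_basis(age_of, n_knots = n_knots)
  bmat <- basis$design                     # tt x p
  p <- ncol(bmat)
  zmat <- cbind(1, seq_len(tt))            # random intercept + slope

  y <- matrix(NA_real_, n, tt)
  y[cbind(match(d$child_id, ids), match(d$visit_index, visits))] <-
    d[[response]]
  has_sex <- use_sex && "sex" %in% names(panel)
  sex <- if (has_sex) {
    vapply(ids, function(i) panel$sex[panel$child_id == i][1L], numeric(1))
  } else rep(0, n)
  if (has_sex && stats::var(sex) < 1e-12) has_sex <- FALSE

  obs <- !is.na(y)
  if (any(rowSums(obs) == 0L)) stop("every child needs >= 1 observation")
  pattern <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(n), pattern)

  run_em <- function(rseed, first_restart = FALSE) {
    set.seed(rseed)
    mstep_mean <- function(w, bhat_list) {
      np <- p * K + has_sex
      a_mat <- matrix(0, np, np); rhs <- numeric(np)
      for (gn in names(groups)) {
        g <- groups[[gn]]
        s <- as.integer(strsplit(gn, ",")[[1L]])
        bs <- bmat[s, , drop = FALSE]; zs <- zmat[s, , drop = FALSE]
        ys <- y[g, s, drop = FALSE]
        for (k in seq_len(K)) {
          wk <- w[g, k]
          u <- ys - bhat_list[[gn]][[k]] %*% t(zs)
          i1 <- (k - 1L) * p + seq_len(p)
          a_mat[i1, i1] <- a_mat[i1, i1] + sum(wk) * crossprod(bs)
          rhs[i1] <- rhs[i1] + as.vector(crossprod(bs, colSums(u * wk)))
          if (has_sex) {
            ws <- sum(wk * sex[g])
            a_mat[i1, np] <- a_mat[i1, np] + ws * colSums(bs)
            a_mat[np, i1] <- a_mat[i1, np]
            a_mat[np, np] <- a_mat[np, np] +
              sum(wk * sex[g]^2) * length(s)
            rhs[np] <- rhs[np] + sum(wk * sex[g] * rowSums(u))
          }
        }
      }
      theta <- solve(a_mat, rhs)
      list(beta = matrix(theta[seq_len(p * K)], p, K),
           gam = if (has_sex) theta[np] else 0)
    }
    # init: k-means on child-level summaries (first restart) or perturbed
    # k-means labels (later restarts); pure random assignment collapses all
    # classes onto the grand mean
    feats <- cbind(rowMeans(y, na.rm = TRUE),
                   apply(y, 1L, function(r) {
                     s <- which(!is.na(r))
                     if (length(s) < 2L) return(0)
                     stats::cov(s, r[s]) / stats::var(s)
                   }))
    lab <- if (K == 1L) rep(1L, n) else {
      stats::kmeans(base::scale(feats), centers = K, nstart = 5L)$cluster
    }
    if (!first_restart && K > 1L) {
      flip <- sample.int(n, ceiling(n / 4))
      lab[flip] <- sample.int(K, length(flip), replace = TRUE)
    }
    w <- matrix(0, n, K); w[cbind(seq_len(n), lab)] <- 1
    pi_k <- colMeans(w)
    gmat <- diag(c(0.3, 0.02))
    sig2 <- max(0.1, stats::var(y[obs]) / 2)
    zero_bhat <- lapply(groups, function(g) {
      lapply(seq_len(K), function(k) matrix(0, length(g), 2L))
    })
    init <- mstep_mean(w, zero_bhat)
    beta <- init$beta; gam <- init$gam
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      # ---- E-step ----
      logf <- matrix(0, n, K)
      bhat_list <- list(); vb_list <- list(); trzvz <- list()
      vinv_list <- list(); logdet_list <- list()
      for (gn in names(groups)) {
        g <- groups[[gn]]
        s <- as.integer(strsplit(gn, ",")[[1L]])
        m <- length(s)
        bs <- bmat[s, , drop = FALSE]; zs <- zmat[s, , drop = FALSE]
        v <- zs %*% gmat %*% t(zs) + diag(sig2, m)
        ch <- chol(v)
        vinv <- chol2inv(ch)
        logdet <- 2 * sum(log(diag(ch)))
        gz <- gmat %*% t(zs)                 # 2 x m
        vb <- gmat - gz %*% vinv %*% t(gz)
        vb_list[[gn]] <- vb
        vinv_list[[gn]] <- vinv
        logdet_list[[gn]] <- logdet
        trzvz[[gn]] <- sum(diag(zs %*% vb %*% t(zs)))
        ys <- y[g, s, drop = FALSE]
        bl <- list()
        for (k in seq_len(K)) {
          mu <- as.vector(bs %*% beta[, k])
          r <- ys - matrix(mu, length(g), m, byrow = TRUE) -
            gam * sex[g]
          q <- rowSums((r %*% vinv) * r)
          logf[g, k] <- -0.5 * (m * log(2 * pi) + logdet + q)
          bl[[k]] <- r %*% vinv %*% t(gz)    # n_g x 2 posterior b means
        }
        bhat_list[[gn]] <- bl
      }
      lw <- sweep(logf, 2L, log(pmax(pi_k, 1e-300)), "+")
      ll <- sum(logsumexp(lw))
      w <- exp(lw - logsumexp(lw))
      if (any(colMeans(w) < 1 / (10 * n))) {
        return(list(ok = FALSE, reason = "empty class"))
      }
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && ll < ll_old - 1e-8 * (abs(ll_old) + 1)) {
        stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
      }
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      # ---- M-step (exact conditional maximizations) ----
      pi_k <- colMeans(w)
      up <- mstep_mean(w, bhat_list)
      beta <- up$beta; gam <- up$gam
      gnum <- matrix(0, 2, 2); rss <- 0; ntot <- 0
      for (gn in names(groups)) {
        g <- groups[[gn]]
        s <- as.integer(strsplit(gn, ",")[[1L]])
        bs <- bmat[s, , drop = FALSE]; zs <- zmat[s, , drop = FALSE]
        ys <- y[g, s, drop = FALSE]
        for (k in seq_len(K)) {
          wk <- w[g, k]
          bh <- bhat_list[[gn]][[k]]
          gnum <- gnum + crossprod(bh * sqrt(wk)) + sum(wk) * vb_list[[gn]]
          mu <- as.vector(bs %*% beta[, k])
          r <- ys - matrix(mu, length(g), length(s), byrow = TRUE) -
            gam * sex[g] - bh %*% t(zs)
          rss <- rss + sum(wk * rowSums(r^2)) + sum(wk) * trzvz[[gn]]
        }
        ntot <- ntot + length(g) * length(s)
      }
      gmat <- (gnum + t(gnum)) / (2 * n)
      ev <- eigen(gmat, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-10) gmat <- gmat + diag(1e-8, 2)
      sig2 <- max(rss / ntot, 1e-8)
    }
    # ---- mean polish: GLS steps at the final variance components ----
    # The residual M-step above converges to, but lags, the GLS fixed
    # point; a few marginal-likelihood EM steps (class labels as the only
    # missing data) make the trajectories exactly generalized least
    # squares at the fitted V, and keep the log-likelihood monotone.
    eval_ll <- function(beta, gam) {
      logf <- matrix(0, n, K)
      for (gn in names(groups)) {
        g <- groups[[gn]]
        s <- as.integer(strsplit(gn, ",")[[1L]])
        bs <- bmat[s, , drop = FALSE]
        ys <- y[g, s, drop = FALSE]
        for (k in seq_len(K)) {
          r <- ys - matrix(as.vector(bs %*% beta[, k]), length(g),
                           length(s), byrow = TRUE) - gam * sex[g]
          logf[g, k] <- -0.5 * (length(s) * log(2 * pi) +
                                  logdet_list[[gn]] +
                                  rowSums((r %*% vinv_list[[gn]]) * r))
        }
      }
      lw <- sweep(logf, 2L, log(pmax(pi_k, 1e-300)), "+")
      list(ll = sum(logsumexp(lw)), w = exp(lw - logsumexp(lw)))
    }
    gls_mean <- function(w) {
      np <- p * K + has_sex
      a_mat <- matrix(0, np, np); rhs <- numeric(np)
      for (gn in names(groups)) {
        g <- groups[[gn]]
        s <- as.integer(strsplit(gn, ",")[[1L]])
        bs <- bmat[s, , drop = FALSE]
        vinv <- vinv_list[[gn]]
        ys <- y[g, s, drop = FALSE]
        bvb <- t(bs) %*% vinv %*% bs
        bv1 <- t(bs) %*% rowSums(vinv)
        v11 <- sum(vinv)
        for (k in seq_len(K)) {
          wk <- w[g, k]
          i1 <- (k - 1L) * p + seq_len(p)
          a_mat[i1, i1] <- a_mat[i1, i1] + sum(wk) * bvb
          rhs[i1] <- rhs[i1] +
            as.vector(t(bs) %*% vinv %*% colSums(ys * wk))
          if (has_sex) {
            ws <- sum(wk * sex[g])
            a_mat[i1, np] <- a_mat[i1, np] + ws * bv1
            a_mat[np, i1] <- a_mat[i1, np]
            a_mat[np, np] <- a_mat[np, np] + sum(wk * sex[g]^2) * v11
            rhs[np] <- rhs[np] +
              sum(wk * sex[g] * (ys %*% rowSums(vinv)))
          }
        }
      }
      theta <- solve(a_mat, rhs)
      list(beta = matrix(theta[seq_len(p * K)], p, K),
           gam = if (has_sex) theta[np] else 0)
    }
    if (length(vinv_list)) {
      for (pol in 1:5) {
        cur <- eval_ll(beta, gam)
        w <- cur$w
        pi_k <- colMeans(w)
        upd <- gls_mean(w)
        moved <- max(abs(upd$beta - beta), abs(upd$gam - gam))
        beta <- upd$beta; gam <- upd$gam
        if (moved < 1e-12) break
      }
      fin <- eval_ll(beta, gam)
      w <- fin$w
      ll_trace <- c(ll_trace, fin$ll)
      ll_old <- fin$ll
    }
    list(ok = TRUE, loglik = ll_old, ll_trace = ll_trace, beta = beta,
         gam = gam, gmat = gmat, sig2 = sig2, pi = pi_k, w = w,
         converged = converged, n_iter = length(ll_trace))
  }

  set.seed(seed)
  rseeds <- sample.int(.Machine$integer.max, n_restarts + 5L)
  best <- NULL; used <- 0L
  for (rs in rseeds) {
    fit <- run_em(rs, first_restart = used == 0L)
    if (!fit$ok) next
    used <- used + 1L
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (used >= n_restarts) break
  }
  if (is.null(best)) stop("all EM restarts collapsed to an empty class")

  # deterministic relabelling: ascending trajectory at the first visit
  mu1 <- as.vector(bmat[1L, , drop = FALSE] %*% best$beta)
  ord <- order(mu1)
  beta <- best$beta[, ord, drop = FALSE]
  pi_k <- best$pi[ord]
  w <- best$w[, ord, drop = FALSE]

  npar <- p * K + (K - 1L) + 3L + 1L + as.integer(has_sex)
  ll <- best$loglik
  structure(list(
    K = K, pi = pi_k, trajectories = beta, sex_effect = best$gam,
    ranef_cov = best$gmat, sigma = sqrt(best$sig2),
    posterior = w, class_modal = max.col(w), children = ids,
    loglik = ll, ll_trace = best$ll_trace, n_par = npar,
    AIC = -2 * ll + 2 * npar, BIC = -2 * ll + log(n) * npar,
    converged = best$converged, n_restarts = used, seed = seed,
    basis = basis, visit_ages = age_of, response = response
  ), class = "latent_class_model")
}

#' @export
print.latent_class_model <- function(x, ...) {
  cat("latent-class mixed model:", x$response, "with K =", x$K,
      "classes\n  pi:", paste(signif(x$pi, 3), collapse = " "),
      "\n  loglik:", signif(x$loglik, 8), " AIC:", signif(x$AIC, 8),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Select the number of latent classes by AIC
#'
#' Fits [fit_latent_class_mixed()] for each candidate K with a shared seed
#' and returns the fit minimizing AIC together with the full criterion
#' table; non-converged fits are flagged but still compared.
#'
#' @param panel,response Passed to [fit_latent_class_mixed()].
#' @param k_range Candidate class counts (default 2:4).
#' @param ... Further arguments for [fit_latent_class_mixed()].
#' @return List with `best` (a `latent_class_model`) and `criteria`
#'   (data.frame K, loglik, n_par, AIC, BIC, converged).
#' @export
select_num_classes <- function(panel, response, k_range = 2:4, ...) {
  stopifnot(length(k_range) >= 1L)
  fits <- lapply(k_range, function(k) {
    fit_latent_class_mixed(panel, response, K = k, ...)
  })
  criteria <- data.frame(
    K = k_range,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_par = vapply(fits, `[[`, numeric(1), "n_par"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    BIC = vapply(fits, `[[`, numeric(1), "BIC"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  list(best = fits[[which.min(criteria$AIC)]], criteria = criteria)
}
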