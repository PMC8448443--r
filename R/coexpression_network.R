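#' Signed weighted adjacency from lipid intensities
#'
#' Builds the signed weighted correlation network: the pairwise Pearson
#' correlation s_ij (pairwise-complete observations) is mapped through the
#' soft-thresholding power transform a_ij = ((1 + s_ij) / 2)^beta, which
#' suppresses weak and negative correlations while amplifying strong
#' positive ones. The diagonal is set to 1.
#'
#' @param x Numeric matrix, samples x lipids. Columns are standardized
#'   (z-scored) internally; correlation is scale-invariant either way.
#' @param beta Soft-thresholding power (default 18, the value that gives
#'   approximate scale-free topology for a signed lipid network).
#' @return Symmetric matrix of class `adjacency` with entries in [0, 1],
#'   unit diagonal, and attributes `beta` and `signed`.
#' @export
signed_adjacency <- function(x, beta = 18) {
  x <- as.matrix(x)
  stopifnot(beta > 0)
  n_ok <- colSums(!is.na(x))
  if (any(n_ok < 3L)) stop("each lipid needs >= 3 non-missing values")
  s <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  if (anyNA(s)) {
    warning("constant column(s): undefined correlations set to 0")
    s[is.na(s)] <- 0
  }
  a <- ((1 + s) / 2)^beta
  diag(a) <- 1
  a <- (a + t(a)) / 2
  structure(a, beta = beta, signed = TRUE, class = c("adjacency", "matrix"))
}

#' Scale-free topology fit of a weighted network
#'
#' Computes weighted connectivities k_i = sum_{j != i} a_ij, bins log10(k)
#' into `n_bins` equal-width bins, and returns the R-squared of the linear
#' regression of log10 bin frequency on log10 mean connectivity -- the usual
#' check that the network approximates a scale-free degree distribution
#' (r^2 of roughly 0.8 or above is considered adequate for biological
#' networks).
#'
#' @param adj An [signed_adjacency()] matrix (or any symmetric weighted
#'   adjacency with unit diagonal).
#' @param n_bins Number of connectivity bins (default 10).
#' @return R-squared in [0, 1]; degenerate connectivity returns 0 with a
#'   warning.
#' @export
scale_free_fit <- function(adj, n_bins = 10L) {
  a <- unclass(adj)
  stopifnot(nrow(a) >= 20L)
  k <- colSums(a) - diag(a)
  if (diff(range(k)) < 1e-12 || any(k <= 0)) {
    warning("degenerate connectivity: scale-free fit undefined, returning 0")
    return(0)
  }
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) {
    warning("too few occupied bins for a scale-free fit, returning 0")
    return(0)
  }
  fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
  summary(fit)$r.squared
}

#' Topological overlap dissimilarity
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) computed
#' with a zeroed diagonal; nodes that share neighbours are considered close
#' even when not directly connected. Returns the dissimilarity 1 - TOM with
#' zero diagonal, the standard clustering input for weighted correlation
#' networks.
#'
#' @param adj An adjacency matrix as from [signed_adjacency()].
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
topological_overlap <- function(adj) {
  a <- unclass(adj)
  diag(a) <- 0
  k <- colSums(a)
  shared <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  d <- 1 - tom
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- dimnames(adj)
  d
}

#' Detect lipid modules by hierarchical clustering
#'
#' Average-linkage hierarchical clustering of the dissimilarity matrix,
#' cut at a fixed fraction of the maximum merge height, followed by
#' pruning: clusters smaller than `min_size` are dissolved into module 0
#' (the unassigned / "grey" pool). Surviving modules are relabelled 1, 2,
#' ... by decreasing size.
#'
#' @param dissim Symmetric dissimilarity matrix with zero diagonal,
#'   typically from [topological_overlap()].
#' @param min_size Minimum lipids per module (default 10).
#' @param cut_height Fraction of the maximum merge height at which the tree
#'   is cut (default 0.99).
#' @return An object of class `module_partition`: integer `assignment`
#'   (named by lipid, 0 = unassigned), `min_size`, `cut_height`, and the
#'   `hclust` merge record in `dendrogram`.
#' @export
detect_modules <- function(dissim, min_size = 10L, cut_height = 0.99) {
  d <- as.matrix(dissim)
  stopifnot(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(abs(diag(d)) < 1e-12))
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- paste0("lipid_", seq_len(n))
  if (n < min_size) {
    warning("fewer lipids than min_size: all unassigned")
    assignment <- stats::setNames(rep(0L, n), rownames(d))
    return(structure(list(assignment = assignment, min_size = min_size,
                          cut_height = cut_height, dendrogram = NULL),
                     class = "module_partition"))
  }
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  h <- cut_height * max(tree$height)
  raw_lab <- stats::cutree(tree, h = h)
  sizes <- table(raw_lab)
  keep <- names(sizes)[sizes >= min_size]
  assignment <- rep(0L, n)
  if (length(keep)) {
    ord <- keep[order(sizes[keep], decreasing = TRUE)]
    for (m in seq_along(ord)) assignment[raw_lab == as.integer(ord[m])] <- m
  }
  names(assignment) <- rownames(d)
  structure(list(assignment = assignment, min_size = as.integer(min_size),
                 cut_height = cut_height, dendrogram = tree),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- table(x$assignment)
  cat("module_partition:", sum(x$assignment > 0), "of",
      length(x$assignment), "lipids in", sum(names(tab) != "0"),
      "modules (min size", x$min_size, ")\n")
  print(tab)
  invisible(x)
}

#' Module eigenlipids via singular value decomposition
#'
#' For each module, the eigenlipid ME_q is the leading left singular vector
#' of the standardized samples x lipids submatrix, rescaled to unit sample
#' variance, with the sign fixed so that its correlation with the module's
#' mean profile is nonnegative. The variance explained is the leading
#' squared singular value's share of the total. Missing intensities are
#' mean-imputed per lipid before decomposition (logged).
#'
#' @param x Numeric matrix, samples x lipids (columns matching
#'   `names(partition$assignment)`).
#' @param partition A [detect_modules()] result.
#' @param include_unassigned Also summarize the unassigned pool (module 0,
#'   labelled `ME0`) when it has >= 2 members; mirrors treating the grey
#'   module as one more node of the module network. Default TRUE.
#' @return An object of class `eigenlipid_matrix`: `values`
#'   (samples x modules, columns ME1, ME2, ..., plus ME0 last if included)
#'   and `variance_explained` per module.
#' @export
module_eigenlipids <- function(x, partition, include_unassigned = TRUE) {
  stopifnot(inherits(partition, "module_partition"))
  x <- as.matrix(x)
  assign <- partition$assignment
  if (!is.null(colnames(x))) {
    stopifnot(all(names(assign) %in% colnames(x)))
    x <- x[, names(assign), drop = FALSE]
  } else {
    stopifnot(ncol(x) == length(assign))
  }
  mods <- sort(unique(assign[assign > 0L]))
  if (include_unassigned && sum(assign == 0L) >= 2L) mods <- c(mods, 0L)
  if (!length(mods)) stop("no modules with >= 2 members")

  if (anyNA(x)) {
    message("missing intensities mean-imputed per lipid before SVD")
    for (j in seq_len(ncol(x))) {
      mis <- is.na(x[, j])
      if (any(mis)) x[mis, j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  me <- matrix(NA_real_, nrow(x), length(mods))
  ve <- numeric(length(mods))
  for (m in seq_along(mods)) {
    sub <- x[, assign == mods[m], drop = FALSE]
    if (ncol(sub) < 2L) stop("module ", mods[m], " has < 2 members")
    sub <- scale(sub)
    sub[is.na(sub)] <- 0  # constant lipids contribute nothing
    sv <- svd(sub, nu = 1L, nv = 0L)
    v <- sv$u[, 1L]
    v <- v / stats::sd(v)
    mp <- rowMeans(sub)
    if (stats::sd(mp) > 0 && stats::cor(v, mp) < 0) v <- -v
    me[, m] <- v
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  colnames(me) <- paste0("ME", mods)
  names(ve) <- colnames(me)
  structure(list(values = me, variance_explained = ve,
                 modules = mods),
            class = "eigenlipid_matrix")
}

#' Intermodular correlation network
#'
#' Pairwise Pearson correlations among eigenlipids, returned as a weighted
#' edge list plus an average-linkage leaf ordering of the modules for
#' heatmap export.
#'
#' @param me An [module_eigenlipids()] result or a plain numeric matrix of
#'   eigenlipid columns.
#' @return List with `edges` (data.frame from, to, weight), `cor` (the
#'   correlation matrix) and `ordering` (module names in dendrogram order).
#' @export
module_network <- function(me) {
  v <- if (inherits(me, "eigenlipid_matrix")) me$values else as.matrix(me)
  if (ncol(v) < 2L) stop("need >= 2 modules for a module network")
  cc <- stats::cor(v)
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  edges <- data.frame(
    from = colnames(cc)[idx[, 1L]],
    to = colnames(cc)[idx[, 2L]],
    weight = cc[idx]
  )
  tree <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  list(edges = edges, cor = cc, ordering = colnames(cc)[tree$order])
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones. Used throughout the recovery tests.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
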