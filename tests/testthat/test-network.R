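test_that("adjacency endpoint identities and beta monotonicity hold", {
  set.seed(1)
  a <- rnorm(50)
  b <- 2 * a + 1          # cor +1
  c1 <- -a                # cor -1
  r <- rnorm(50)
  z <- residuals(lm(r ~ a))  # cor exactly 0 with a
  x <- cbind(a, b, c1, z)
  adj <- signed_adjacency(x, beta = 18)
  expect_equal(adj["a", "b"], 1, tolerance = 1e-10)
  expect_equal(adj["a", "c1"], 0, tolerance = 1e-10)
  expect_equal(adj["a", "z"], 0.5^18, tolerance = 1e-8)
  expect_equal(attr(signed_adjacency(x), "beta"), 18)  # default power

  a6 <- signed_adjacency(x, beta = 6)
  a18 <- signed_adjacency(x, beta = 18)
  expect_true(all(a18 <= a6 + 1e-12))  # higher power shrinks entries
})

test_that("adjacency invariants hold on random inputs", {
  for (s in 1:5) {
    x <- gen_planted_blocks(60, per = 8, blocks = 2, r = 0.5, seed = s)
    adj <- signed_adjacency(x, beta = 10)
    expect_true(all(adj >= 0 & adj <= 1))
    expect_equal(unclass(adj), t(unclass(adj)))
    expect_equal(unname(diag(adj)), rep(1, ncol(x)))
  }
  expect_warning(signed_adjacency(cbind(rnorm(10), rep(1, 10))),
                 "constant")
})

test_that("scale-free fit separates power-law from degenerate networks", {
  n <- 200
  kt <- (1:n)^(-0.9)
  a <- outer(kt / max(kt), kt / max(kt))
  diag(a) <- 1
  expect_gte(scale_free_fit(a), 0.8)
  eq <- matrix(0.5, 30, 30); diag(eq) <- 1
  expect_warning(r2 <- scale_free_fit(eq), "degenerate")
  expect_identical(r2, 0)
})

test_that("topological overlap matches a brute-force oracle", {
  # 4-node worked example, evaluated independently element by element
  a <- matrix(c(1, .8, .3, .1,
                .8, 1, .5, .2,
                .3, .5, 1, .6,
                .1, .2, .6, 1), 4, 4)
  d <- topological_overlap(a)
  a0 <- a; diag(a0) <- 0
  k <- colSums(a0)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) {
      expect_identical(d[i, j], 0)
    } else {
      num <- sum(a0[i, -c(i, j)] * a0[-c(i, j), j]) + a0[i, j]
      tom <- num / (min(k[i], k[j]) + 1 - a0[i, j])
      expect_equal(d[i, j], 1 - tom, tolerance = 1e-12)
    }
  }

  # identical binary connection patterns with a_ij = 1 -> dissimilarity 0
  b <- matrix(0, 4, 4)
  b[1, 2] <- b[2, 1] <- 1
  b[1, 3] <- b[3, 1] <- b[2, 3] <- b[3, 2] <- 1
  diag(b) <- 1
  expect_equal(topological_overlap(b)[1, 2], 0, tolerance = 1e-12)

  # unconnected pair with no shared neighbours -> dissimilarity 1
  c2 <- diag(4)
  c2[1, 2] <- c2[2, 1] <- 0
  c2[3, 4] <- c2[4, 3] <- 0.5
  expect_equal(topological_overlap(c2)[1, 2], 1, tolerance = 1e-12)
})

test_that("planted modules are recovered exactly; small blocks dissolve", {
  x <- gen_planted_blocks(400, per = 20, blocks = 3, r = 0.8, seed = 11)
  part <- detect_modules(topological_overlap(
    signed_adjacency(scale(x), 18)), min_size = 10)
  expect_equal(adjusted_rand_index(part$assignment,
                                   rep(1:3, each = 20)), 1)
  expect_equal(sort(unique(part$assignment)), 1:3)

  # a planted block of 5 with min_size 10 ends up unassigned
  x2 <- cbind(gen_planted_blocks(300, per = 20, blocks = 2, r = 0.8,
                                 seed = 3),
              gen_planted_blocks(300, per = 5, blocks = 1, r = 0.8,
                                 seed = 4))
  part2 <- detect_modules(topological_overlap(
    signed_adjacency(scale(x2), 18)), min_size = 10)
  expect_true(all(part2$assignment[41:45] == 0L))

  expect_warning(p3 <- detect_modules(matrix(0, 3, 3), min_size = 10),
                 "fewer lipids")
  expect_true(all(p3$assignment == 0L))
})

test_that("module recovery is stable across seeds (ARI >= 0.95)", {
  aris <- vapply(1:10, function(s) {
    x <- gen_planted_blocks(400, per = 20, blocks = 3, r = 0.8, seed = s)
    part <- detect_modules(topological_overlap(
      signed_adjacency(scale(x), 18)), min_size = 10)
    adjusted_rand_index(part$assignment, rep(1:3, each = 20))
  }, numeric(1))
  expect_true(all(aris >= 0.95))
})

test_that("eigenlipids match the PCA oracle and sign convention", {
  x <- gen_planted_blocks(200, per = 15, blocks = 2, r = 0.7, seed = 21)
  part <- detect_modules(topological_overlap(
    signed_adjacency(scale(x), 18)), min_size = 10)
  me <- module_eigenlipids(scale(x), part, include_unassigned = FALSE)
  for (q in 1:2) {
    sub <- scale(x[, part$assignment == q])
    ev <- eigen(cov(sub), symmetric = TRUE)$values
    expect_equal(unname(me$variance_explained[q]), ev[1] / sum(ev),
                 tolerance = 1e-8)
    # no unit-norm combination beats the leading component
    expect_gte(ev[1] / sum(ev), var(sub %*% rep(1 / sqrt(ncol(sub)),
                                                ncol(sub))) / sum(ev) - 1e-8)
    expect_gte(cor(me$values[, q], rowMeans(sub)), 0)
  }

  # module of identical columns: ME is that column, standardized
  y <- rnorm(80)
  xid <- cbind(y, y, y, gen_planted_blocks(80, per = 12, blocks = 1,
                                           r = 0.9, seed = 5))
  part2 <- structure(list(assignment = setNames(
    c(1L, 1L, 1L, rep(2L, 12)), colnames(xid) <- paste0("c", 1:15)),
    min_size = 3L), class = "module_partition")
  me2 <- module_eigenlipids(xid, part2, include_unassigned = FALSE)
  expect_equal(me2$values[, 1], as.vector(scale(y)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(me2$variance_explained[1]), 1, tolerance = 1e-12)
})

test_that("module network weights behave at the null and at identity", {
  y <- rnorm(300)
  me_id <- cbind(ME1 = y, ME2 = y)
  expect_equal(module_network(me_id)$edges$weight, 1, tolerance = 1e-12)

  set.seed(2)
  me_null <- matrix(rnorm(1000 * 4), 1000, 4,
                    dimnames = list(NULL, paste0("ME", 1:4)))
  expect_true(all(abs(module_network(me_null)$edges$weight) < 0.1))
})
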