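test_that("normalization matches direct evaluation of log(x/total + 0.1)", {
  cm <- tiny_counts(rbind(c(1, 1, 0), c(2, 0, 2)))
  out <- normalize_expression(cm, n_hvg = 10)
  expect_equal(out$matrix[1, 1], log(0.5 + 0.1))
  expect_equal(out$matrix[1, 3], log(0.1))
  expect_equal(out$matrix[2, 1], log(2 / 4 + 0.1))
  # n_hvg >= n_genes keeps the whole universe
  expect_equal(ncol(out$matrix), 3)
})

test_that("zero-total cells and bad n_hvg are rejected by name", {
  cm <- tiny_counts(rbind(c(1, 1), c(0, 0)),)
  expect_error(normalize_expression(cm), "cell_2")
  cm2 <- tiny_counts(rbind(c(1, 1), c(1, 2)))
  expect_error(normalize_expression(cm2, n_hvg = 0), "n_hvg")
})

test_that("hvg selection retains the requested number of most variable genes", {
  set.seed(1)
  n <- 100
  base <- matrix(rpois(n * 20, 5), n, 20)
  noisy <- matrix(rpois(n * 5, c(1, 60)), n, 5)  # alternating extremes
  cm <- tiny_counts(cbind(base, noisy))
  out <- normalize_expression(cm, n_hvg = 8)
  expect_length(out$genes, 8)
  expect_equal(ncol(out$matrix), 8)
})

test_that("PCA embedding matches dense eigendecomposition on small input", {
  set.seed(2)
  x <- matrix(rnorm(40 * 6), 40, 6)
  emb <- compute_embedding(x, "rna", n_components = 3)
  ctr <- sweep(x, 2, colMeans(x))
  ev <- eigen(cov(x))
  scores <- ctr %*% ev$vectors[, 1:3]
  for (c in 1:3) {
    expect_lt(min(sum((emb$coords[, c] - scores[, c])^2),
                  sum((emb$coords[, c] + scores[, c])^2)), 1e-8)
  }
  expect_equal(emb$component_variances, ev$values[1:3], tolerance = 1e-8)
})

test_that("identical cells give an all-zero embedding; collinear cells load one component", {
  x <- matrix(1, 20, 4)
  emb <- compute_embedding(x, "rna", n_components = 2)
  expect_true(all(emb$component_variances == 0))
  expect_true(all(emb$coords == 0))
  # points on a line: first component carries all variance
  y <- cbind(seq_len(20), 2 * seq_len(20))
  emb2 <- compute_embedding(y, "rna", n_components = 1)
  expect_equal(sum(emb2$component_variances),
               sum(eigen(cov(y))$values), tolerance = 1e-8)
})

test_that("ATAC embedding drops a depth-correlated first component and reports it", {
  set.seed(3)
  n <- 80
  depth <- exp(rnorm(n, log(100), 1))
  m <- matrix(rpois(n * 50, outer(depth / 50, rep(1, 50))), n, 50)
  m[m < 0] <- 0
  cm <- tiny_counts(m, modality = "atac")
  emb <- compute_embedding(cm, "atac", n_components = 5)
  expect_true(is.finite(emb$depth_correlation))
  expect_equal(emb$n_components, 5)
  expect_true(all(diff(emb$component_variances) <= 1e-12))
})

test_that("kNN graph matches exhaustive distances and honors k bounds", {
  pts <- matrix(c(0, 1, 3), 3, 1)
  gr <- build_knn_graph(pts, k = 1)
  expect_equal(gr$index[, 1], c(2L, 1L, 2L))
  expect_equal(gr$nn_dist[, 1], c(1, 1, 2))
  # k = n - 1 gives the complete graph minus self-loops
  gr2 <- build_knn_graph(pts, k = 2)
  expect_equal(sort(gr2$index[1, ]), c(2L, 3L))
  expect_error(build_knn_graph(pts, k = 3), "k <= n - 1")
  # agreement with brute-force distances on random points
  set.seed(4)
  x <- matrix(rnorm(30 * 3), 30, 3)
  gr3 <- build_knn_graph(x, k = 5)
  d <- as.matrix(dist(x))
  for (i in c(1, 13, 30)) {
    expect_setequal(gr3$index[i, ], setdiff(order(d[i, ]), i)[1:5])
  }
})

test_that("adaptive kernel follows the closed form and is symmetric on mutual support", {
  # two mutual neighbors at squared distance 2 with sigma_i + sigma_j = 2
  pts <- matrix(c(0, sqrt(2), 10), 3, 1)
  gr <- build_knn_graph(pts, k = 2)
  kern <- compute_adaptive_kernel(gr, l = 1)
  s1 <- gr$nn_dist[1, 1]; s2 <- gr$nn_dist[2, 1]
  expect_equal(s1 + s2, 2 * sqrt(2))
  expected <- exp(-0.5 * 2 / (s1 + s2)) / sqrt(2 * pi * (s1 + s2))
  expect_equal(kern$affinities[1, 2], expected)
  m <- kern$affinities
  expect_equal(max(abs(m - Matrix::t(m))), 0)
  # diagonal holds the zero-distance kernel value
  expect_equal(m[1, 1], 1 / sqrt(4 * pi * kern$bandwidths[1]))
})

test_that("kernel support is restricted to mutual neighbors", {
  set.seed(5)
  x <- matrix(rnorm(40 * 2), 40, 2)
  gr <- build_knn_graph(x, k = 4)
  kern <- compute_adaptive_kernel(gr, l = 2)
  m <- kern$affinities
  idx <- gr$index
  tm <- as(as(m, "TsparseMatrix"), "generalMatrix")
  off <- which(tm@i != tm@j)
  for (e in off[seq_len(min(50, length(off)))]) {
    i <- tm@i[e] + 1; j <- tm@j[e] + 1
    expect_true(j %in% idx[i, ] && i %in% idx[j, ])
  }
  # union support is a superset of mutual support
  kern_u <- compute_adaptive_kernel(gr, l = 2, support = "union")
  expect_gte(length(kern_u$affinities@x), length(m@x))
})

test_that("bandwidths grow with l and degenerate duplicates are repaired", {
  set.seed(6)
  x <- matrix(rnorm(30 * 2), 30, 2)
  gr <- build_knn_graph(x, k = 6)
  s2 <- compute_adaptive_kernel(gr, l = 2)$bandwidths
  s5 <- compute_adaptive_kernel(gr, l = 5)$bandwidths
  expect_true(all(s5 >= s2))
  # duplicated points: sigma floor replaces zeros with smallest positive
  xd <- rbind(x, x[1:3, ])
  grd <- build_knn_graph(xd, k = 6)
  kd <- compute_adaptive_kernel(grd, l = 1)
  expect_true(all(kd$bandwidths > 0))
  expect_error(compute_adaptive_kernel(gr, l = 6), "l must satisfy")
})

test_that("diffusion map has unit leading eigenvalue and separates disconnected blocks", {
  kern <- block_kernel(n_per_block = 8)
  dm <- suppressWarnings(diffusion_map(kern, n_dcs = 3))
  expect_true(all(abs(dm$eigenvalues) <= 1 + 1e-9))
  # top retained component separates the two blocks
  top <- dm$dcs[, 1]
  expect_true(max(top[1:8]) < min(top[9:16]) || min(top[1:8]) > max(top[9:16]))
  # agreement with a dense eigensolver: transition rows sum to 1
  m <- kern$affinities
  p <- as.matrix(m / Matrix::rowSums(m))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-12)
  ev <- eigen(p)
  expect_equal(sort(abs(dm$eigenvalues), decreasing = TRUE)[1], 1, tolerance = 1e-9)
  expect_error(diffusion_map(kern, n_dcs = 16), "n_dcs")
})
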