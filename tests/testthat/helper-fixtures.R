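suppressPackageStartupMessages(library(Matrix))

# well-separated 2-D blobs with an embedding, graph, kernel and diffusion map
blob_pipeline <- function(n_per = 30, n_blobs = 3, sep = 12, k = 8, l = 3,
                          seed = 42) {
  set.seed(seed)
  centers <- cbind(sep * seq_len(n_blobs), sep * (seq_len(n_blobs) %% 2))
  coords <- do.call(rbind, lapply(seq_len(n_blobs), function(b) {
    sweep(matrix(rnorm(n_per * 2), n_per, 2), 2, centers[b, ], "+")
  }))
  state <- rep(seq_len(n_blobs), each = n_per)
  graph <- build_knn_graph(coords, k = k)
  kern <- compute_adaptive_kernel(graph, l = l)
  dm <- suppressWarnings(diffusion_map(kern, n_dcs = 4))
  list(coords = coords, state = state, graph = graph, kernel = kern, dmap = dm)
}

# random symmetric sparse kernel from random points (valid adaptive kernel)
random_kernel <- function(n = 40, k = 8, l = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), n, 3)
  compute_adaptive_kernel(build_knn_graph(x, k = k), l = l)
}

# tiny count matrix with fixed entries
tiny_counts <- function(values, modality = "rna") {
  cell_matrix(values, modality = modality)
}

# kernel of two disjoint blocks of near-identical cells (block archetype oracle)
block_kernel <- function(n_per_block = 3, eps = 1e-3, seed = 7) {
  set.seed(seed)
  n <- 2 * n_per_block
  pts <- rbind(
    matrix(rep(c(0, 0), each = n_per_block), n_per_block, 2) +
      eps * matrix(rnorm(n_per_block * 2), n_per_block, 2),
    matrix(rep(c(10, 10), each = n_per_block), n_per_block, 2) +
      eps * matrix(rnorm(n_per_block * 2), n_per_block, 2))
  graph <- build_knn_graph(pts, k = n - 1)
  compute_adaptive_kernel(graph, l = 2)
}

# dense SRE, the independent oracle for the trace identity
dense_sre <- function(m, a, b) {
  m <- as.matrix(m)
  norm(m - m %*% as.matrix(b) %*% as.matrix(a), "F")^2
}

# exhaustive best SRE over all hard partitions of n cells into s groups
exhaustive_best_sre <- function(kernel, s) {
  m <- kernel$affinities
  n <- nrow(m)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(s)), n))
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < s) next
    a <- sparseMatrix(i = lab, j = seq_len(n), x = 1, dims = c(s, n))
    sizes <- tabulate(lab, s)
    b <- sparseMatrix(i = seq_len(n), j = lab, x = 1 / sizes[lab],
                      dims = c(n, s))
    best <- min(best, dense_sre(m, a, b))
  }
  best
}
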