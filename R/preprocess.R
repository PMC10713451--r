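#' Library-size normalize, log-transform and select variable genes
#'
#' Divides each cell's counts by its total, log-transforms with a pseudocount
#' of 0.1, and keeps the genes with the highest normalized dispersion.
#'
#' @param counts A [cell_matrix()] with `modality = "rna"`.
#' @param n_hvg Number of highly variable genes to retain (default 2500).
#'   When `n_hvg >= n_genes` all genes are kept.
#'
#' @return A list with `matrix` (dense cells x selected genes, entries
#'   `log(count/total + 0.1)`) and `genes` (selected gene ids).
#' @export
normalize_expression <- function(counts, n_hvg = 2500) {
  stopifnot(is(counts, "cell_matrix"))
  if (modality_of(counts) != "rna") abort("normalize_expression expects RNA counts")
  if (n_hvg < 1) abort("n_hvg must be >= 1")
  m <- as_dgc(counts)
  totals <- Matrix::rowSums(m)
  if (any(totals == 0)) {
    abort(sprintf("cell(s) with zero total counts: %s",
                  paste(head(rownames(m)[totals == 0], 5), collapse = ", ")))
  }
  norm <- m / totals
  genes <- select_hvgs(norm, n_hvg)
  out <- as.matrix(norm[, genes, drop = FALSE])
  out <- log(out + 0.1)
  list(matrix = out, genes = genes)
}

# normalized-dispersion ranking on library-size-normalized values:
# dispersion = var/mean per gene, z-scored within 20 equal-occupancy mean bins
select_hvgs <- function(norm, n_hvg) {
  if (n_hvg >= ncol(norm)) return(colnames(norm))
  mu <- Matrix::colMeans(norm)
  ex2 <- Matrix::colMeans(norm^2)
  v <- pmax(ex2 - mu^2, 0) * nrow(norm) / max(1, nrow(norm) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), breaks = 20, labels = FALSE)
  zd <- disp
  for (b in unique(bins)) {
    idx <- which(bins == b)
    s <- sd(disp[idx])
    zd[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  colnames(norm)[order(zd, decreasing = TRUE)[seq_len(n_hvg)]]
}

#' Compute a low-dimensional embedding of cells
#'
#' RNA: principal components of the normalized highly-variable-gene matrix.
#' ATAC: TF-IDF normalization followed by truncated SVD, with the first
#' component dropped when its absolute Pearson correlation with per-cell log
#' total counts exceeds `drop_first_threshold` (it then mostly tracks
#' sequencing depth rather than cell state). The TF-IDF variant used is
#' `tf = count / cell_total` and `idf = log(1 + n_cells / (1 + n_cells_with_feature))`.
#'
#' @param x For `modality = "rna"`, a dense normalized matrix as returned by
#'   [normalize_expression()]`$matrix` (or a raw `cell_matrix`, which is
#'   normalized internally with `n_hvg`). For `modality = "atac"`, a
#'   `cell_matrix` of peak/bin counts.
#' @param modality `"rna"` or `"atac"`.
#' @param n_components Number of components (default 50 for RNA, 30 for ATAC).
#' @param n_hvg Passed to [normalize_expression()] when `x` is a raw RNA
#'   `cell_matrix`.
#' @param drop_first_threshold ATAC only: absolute correlation with log total
#'   counts above which component 1 is excluded (default 0.9). The observed
#'   correlation is always reported.
#' @param seed Seed for the truncated solver.
#'
#' @return An `embedding` object: list with `coords` (cells x components),
#'   `n_components`, `modality`, `component_variances` (non-increasing), and
#'   for ATAC `depth_correlation` and `dropped_first`.
#' @export
compute_embedding <- function(x, modality = c("rna", "atac"),
                              n_components = NULL, n_hvg = 2500,
                              drop_first_threshold = 0.9, seed = 0) {
  modality <- match.arg(modality)
  if (modality == "rna") {
    if (is.null(n_components)) n_components <- 50
    if (is(x, "cell_matrix")) x <- normalize_expression(x, n_hvg)$matrix
    x <- as.matrix(x)
    if (n_components >= min(dim(x))) {
      abort("n_components must be smaller than both the number of cells and features")
    }
    ctr <- sweep(x, 2, colMeans(x))
    tot_var <- sum(ctr^2) / (nrow(x) - 1)
    if (tot_var == 0) {
      scores <- matrix(0, nrow(x), n_components)
    } else {
      scores <- truncated_scores(ctr, n_components, derive_seed(seed, 1))
    }
    rownames(scores) <- rownames(x)
    vars <- apply(scores, 2, var)
    coords <- scores
    dep_cor <- NA_real_; dropped <- FALSE
  } else {
    stopifnot(is(x, "cell_matrix"))
    if (is.null(n_components)) n_components <- 30
    m <- as_dgc(x)
    if (n_components + 1 >= min(dim(m))) {
      abort("n_components must be smaller than both the number of cells and features")
    }
    totals <- Matrix::rowSums(m)
    if (any(totals == 0)) abort("cell(s) with zero total ATAC counts")
    tf <- m / totals
    df <- Matrix::colSums(m > 0)
    idf <- log(1 + nrow(m) / (1 + df))
    xn <- tf %*% Diagonal(x = idf)
    scores <- truncated_scores(xn, n_components + 1, derive_seed(seed, 2),
                               center = FALSE)
    rownames(scores) <- rownames(m)
    dep_cor <- suppressWarnings(cor(scores[, 1], log(totals)))
    dropped <- is.finite(dep_cor) && abs(dep_cor) > drop_first_threshold
    keep <- if (dropped) 2:(n_components + 1) else 1:n_components
    coords <- scores[, keep, drop = FALSE]
    vars <- apply(coords, 2, var)
  }
  ord <- order(vars, decreasing = TRUE)
  structure(list(coords = coords[, ord, drop = FALSE],
                 n_components = ncol(coords),
                 modality = modality,
                 component_variances = vars[ord],
                 depth_correlation = dep_cor,
                 dropped_first = dropped),
            class = "embedding")
}

# truncated SVD scores U %*% diag(d); exact base svd below 200 cells/features,
# implicitly restarted Lanczos (irlba) above
truncated_scores <- function(x, ncomp, seed, center = FALSE) {
  if (min(dim(x)) <= 200) {
    sv <- svd(as.matrix(x), nu = ncomp, nv = 0)
    sv$u %*% diag(sv$d[seq_len(ncomp)], ncomp)
  } else {
    set.seed(seed)
    sv <- irlba::irlba(x, nv = ncomp, nu = ncomp)
    sv$u %*% diag(sv$d, ncomp)
  }
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding [%s]> %d cells x %d components\n",
              x$modality, nrow(x$coords), x$n_components))
  invisible(x)
}

#' Build an exact k-nearest-neighbor graph
#'
#' Euclidean kNN in the embedding; row i of the distance matrix stores the
#' distances to the k nearest non-self cells.
#'
#' @param embedding An `embedding` (or a bare coordinate matrix).
#' @param k Number of neighbors (default 50; must be `<= n - 1`).
#'
#' @return A `neighbor_graph`: list with sparse `distances` (n x n,
#'   `D[i, j] > 0` iff j is among the k nearest neighbors of i), `index`
#'   (n x k neighbor indices), `nn_dist` (n x k distances), and `k`.
#' @export
build_knn_graph <- function(embedding, k = 50) {
  coords <- if (inherits(embedding, "embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  if (n < 2) abort("need at least 2 cells")
  if (k < 1) abort("k must be >= 1")
  if (k >= n) abort(sprintf("k = %d too large for %d cells; use k <= n - 1", k, n))
  nn <- RANN::nn2(coords, coords, k = k + 1, treetype = "kd", searchtype = "standard")
  idx <- nn$nn.idx
  dst <- nn$nn.dists
  # drop the self match; usually column 1, but duplicate points can tie
  out_idx <- idx[, -1, drop = FALSE]
  out_dst <- dst[, -1, drop = FALSE]
  odd <- which(idx[, 1] != seq_len(n))
  for (r in odd) {
    p <- match(r, idx[r, ])
    keep <- if (is.na(p)) seq_len(k) else setdiff(seq_len(k + 1), p)[seq_len(k)]
    out_idx[r, ] <- idx[r, keep]
    out_dst[r, ] <- dst[r, keep]
  }
  d <- sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(out_idx)),
                    x = as.vector(t(out_dst)), dims = c(n, n))
  structure(list(distances = d, index = out_idx, nn_dist = out_dst,
                 k = k, coords = coords),
            class = "neighbor_graph")
}

#' Adaptive Gaussian kernel on a mutual kNN graph
#'
#' Transforms neighbor distances into similarities with a per-cell adaptive
#' bandwidth: `sigma_i` is the distance from cell i to its l-th nearest
#' neighbor. For cells i, j on the supported edge set the affinity is
#' `M_ij = exp(-0.5 * d_ij^2 / (sigma_i + sigma_j)) / sqrt(2 * pi * (sigma_i + sigma_j))`
#' and 0 otherwise. The diagonal carries the kernel value at zero distance,
#' `1 / sqrt(4 * pi * sigma_i)`. Bandwidths below 1e-12 (duplicate points)
#' are replaced by the smallest positive bandwidth in the dataset.
#'
#' @param graph A `neighbor_graph` from [build_knn_graph()].
#' @param l Bandwidth neighbor rank, `1 <= l < k` (default 15). A tuning
#'   knob, not a reported constant.
#' @param support `"mutual"` (default) keeps an edge only when i and j are in
#'   each other's neighbor lists; `"union"` keeps either direction.
#'
#' @return A `kernel_matrix`: list with symmetric sparse `affinities`,
#'   per-cell `bandwidths`, `l`, and `support`.
#' @export
compute_adaptive_kernel <- function(graph, l = 15, support = c("mutual", "union")) {
  support <- match.arg(support)
  stopifnot(inherits(graph, "neighbor_graph"))
  if (l >= graph$k || l < 1) abort(sprintf("l must satisfy 1 <= l < k (k = %d)", graph$k))
  sigma <- graph$nn_dist[, l]
  if (any(sigma < 1e-12)) {
    pos <- sigma[sigma >= 1e-12]
    if (!length(pos)) abort("all bandwidths are non-positive (all points identical?)")
    sigma[sigma < 1e-12] <- min(pos)
  }
  d <- graph$distances
  n <- nrow(d)
  has <- d; has@x <- rep(1, length(has@x))
  dsum <- d + Matrix::t(d)        # identical sparsity pattern as cnt
  cnt <- has + Matrix::t(has)
  i <- rep(seq_len(n), diff(cnt@p))  # dgCMatrix is column-compressed: j runs over cols
  j <- i; i <- cnt@i + 1L
  j <- rep(seq_len(n), diff(cnt@p))
  dij <- dsum@x / cnt@x            # directed distances agree; this de-duplicates
  keep <- if (support == "mutual") cnt@x == 2 else rep(TRUE, length(cnt@x))
  i <- i[keep]; j <- j[keep]; dij <- dij[keep]
  denom <- sigma[i] + sigma[j]
  val <- exp(-0.5 * dij^2 / denom) / sqrt(2 * pi * denom)
  m <- sparseMatrix(i = i, j = j, x = val, dims = c(n, n))
  diag(m) <- 1 / sqrt(4 * pi * sigma)
  structure(list(affinities = m, bandwidths = sigma, l = l, support = support),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %d cells, %d non-zero affinities (l = %d, %s support)\n",
              nrow(x$affinities), length(x$affinities@x), x$l, x$support))
  invisible(x)
}

#' Diffusion map from an affinity kernel
#'
#' Row-normalizes the kernel to a Markov transition operator and returns its
#' leading non-trivial right eigenvectors, ordered by eigenvalue magnitude.
#' The trivial constant eigenvector (eigenvalue 1) is removed; when the graph
#' is disconnected the remaining vectors of the unit eigenspace, which
#' separate the components, are retained.
#'
#' @param kernel A `kernel_matrix`.
#' @param n_dcs Number of diffusion components (default 10).
#' @param seed Seed for the iterative eigensolver.
#'
#' @return A `diffusion_embedding`: list with `dcs` (cells x n_dcs),
#'   `eigenvalues` (non-increasing magnitude), `n_dcs`.
#' @export
diffusion_map <- function(kernel, n_dcs = 10, seed = 0) {
  stopifnot(inherits(kernel, "kernel_matrix"))
  m <- kernel$affinities
  n <- nrow(m)
  if (n_dcs >= n) abort("n_dcs must be smaller than the number of cells")
  deg <- Matrix::rowSums(m)
  if (any(deg == 0)) abort("kernel has isolated cells with zero affinity")
  ncomp <- n_components_graph(m)
  if (ncomp > 1) {
    warn(sprintf("kernel graph has %d connected components", ncomp))
  }
  # symmetric conjugate S = D^-1/2 M D^-1/2 shares eigenvalues with P = D^-1 M
  dhalf <- 1 / sqrt(deg)
  s <- Diagonal(x = dhalf) %*% m %*% Diagonal(x = dhalf)
  s <- (s + Matrix::t(s)) / 2
  k_want <- min(n_dcs + ncomp, n - 1)
  if (n <= 200) {
    eig <- eigen(as.matrix(s), symmetric = TRUE)
    vals <- eig$values; vecs <- eig$vectors
  } else {
    set.seed(derive_seed(seed, 3))
    eig <- RSpectra::eigs_sym(s, k = k_want, which = "LM")
    vals <- eig$values; vecs <- eig$vectors
  }
  ord <- order(abs(vals), decreasing = TRUE)
  vals <- vals[ord]; vecs <- vecs[, ord, drop = FALSE]
  # deflate only the global-constant direction from the unit eigenspace;
  # in S-space the constant right eigenvector of P is D^(1/2) 1
  v0 <- sqrt(deg); v0 <- v0 / sqrt(sum(v0^2))
  unit <- which(abs(vals - 1) < 1e-9)
  if (length(unit)) {
    vt <- vecs[, unit, drop = FALSE]
    vt <- vt - v0 %*% crossprod(v0, vt)
    nrm <- sqrt(colSums(vt^2))
    nz <- which(nrm > 1e-8)
    vt <- if (length(nz)) qr.Q(qr(vt[, nz, drop = FALSE])) else NULL
    n_extra <- if (is.null(vt)) 0 else ncol(vt)
    vecs <- cbind(vt, vecs[, -unit, drop = FALSE])
    vals <- c(rep(1, n_extra), vals[-unit])
  }
  take <- seq_len(min(n_dcs, ncol(vecs)))
  psi <- vecs[, take, drop = FALSE] * dhalf
  # deterministic sign convention: largest-magnitude entry positive
  for (c in seq_len(ncol(psi))) {
    piv <- which.max(abs(psi[, c]))
    if (psi[piv, c] < 0) psi[, c] <- -psi[, c]
  }
  rownames(psi) <- rownames(m)
  structure(list(dcs = psi, eigenvalues = vals[take], n_dcs = ncol(psi)),
            class = "diffusion_embedding")
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat(sprintf("<diffusion_embedding> %d cells x %d components\n",
              nrow(x$dcs), x$n_dcs))
  invisible(x)
}

# number of connected components by BFS on the sparsity pattern
n_components_graph <- function(adj) {
  g <- as(as(adj, "generalMatrix"), "CsparseMatrix")
  n <- nrow(g)
  comp <- integer(n)
  stack <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    top <- 1L; stack[1L] <- start; comp[start] <- cur
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      if (g@p[v + 1L] > g@p[v]) {
        nb <- g@i[(g@p[v] + 1L):g@p[v + 1L]] + 1L
        nb <- nb[comp[nb] == 0L]
        comp[nb] <- cur
        if (length(nb)) {
          stack[(top + 1L):(top + length(nb))] <- nb
          top <- top + length(nb)
        }
      }
    }
  }
  cur
}
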