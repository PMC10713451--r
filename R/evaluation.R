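#' Metacell quality metrics: compactness, separation, purity
#'
#' Compactness of a metacell is the mean over diffusion components of the
#' (population) standard deviation of its member-cell coordinates — lower is
#' better. Separation is the Euclidean distance from the metacell centroid
#' to the nearest other metacell centroid in diffusion space — higher is
#' better. Purity is the frequency of the modal cell type among members.
#'
#' @param assignment A `metacell_assignment` (or integer label vector).
#' @param dcs A `diffusion_embedding` or cells x components matrix.
#' @param celltypes Optional per-cell type labels; purity omitted without.
#' @param separation `"centroid"` (default) measures centroid-to-centroid
#'   distance; `"member"` the closest member-cell pair distance.
#'
#' @return A tibble with one row per metacell: `metacell`, `n_cells`,
#'   `compactness`, `separation`, and `purity`/`celltype` when available.
#' @export
evaluate_metacells <- function(assignment, dcs, celltypes = NULL,
                               separation = c("centroid", "member")) {
  separation <- match.arg(separation)
  labels <- if (inherits(assignment, "metacell_assignment")) assignment$labels else assignment
  coords <- if (inherits(dcs, "diffusion_embedding")) dcs$dcs else as.matrix(dcs)
  ids <- sort(unique(labels))
  members <- split(seq_along(labels), labels)
  comp <- vapply(members, function(ix) {
    sub <- coords[ix, , drop = FALSE]
    mean(apply(sub, 2, function(v) sqrt(mean((v - mean(v))^2))))
  }, numeric(1))
  cent <- t(vapply(members, function(ix) colMeans(coords[ix, , drop = FALSE]),
                   numeric(ncol(coords))))
  sep <- if (length(ids) < 2) {
    rep(NA_real_, length(ids))
  } else if (separation == "centroid") {
    dd <- as.matrix(stats::dist(cent))
    diag(dd) <- Inf
    apply(dd, 1, min)
  } else {
    vapply(seq_along(ids), function(i) {
      own <- coords[members[[i]], , drop = FALSE]
      other <- coords[-members[[i]], , drop = FALSE]
      min(RANN::nn2(other, own, k = 1)$nn.dists)
    }, numeric(1))
  }
  out <- tibble(metacell = ids,
                n_cells = lengths(members),
                compactness = unname(comp),
                separation = unname(sep))
  if (!is.null(celltypes)) {
    ann <- vapply(members, function(ix) {
      tb <- sort(table(as.character(celltypes[ix])), decreasing = TRUE)
      top <- tb[tb == tb[1]]
      c(sort(names(top))[1], unname(tb[1]) / length(ix))
    }, character(2))
    out$celltype <- unname(ann[1, ])
    out$purity <- as.numeric(ann[2, ])
  }
  out
}

#' Normalized mutual information between two labelings
#'
#' `NMI = I(a; b) / mean(H(a), H(b))` with natural logarithms
#' (arithmetic-mean normalization). Invariant to label renaming; 1 for
#' identical partitions, near 0 for independent ones.
#'
#' @param labels_a,labels_b Label vectors over the same cells.
#' @return A score in \[0, 1\].
#' @export
compute_nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) abort("labelings must cover the same cells")
  a <- as.integer(factor(labels_a)); b <- as.integer(factor(labels_b))
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) {
    warn("both labelings have a single cluster; NMI defined as 1")
    return(1)
  }
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  max(0, min(1, mi / ((ha + hb) / 2)))
}

#' Stratify cells and metacells by local density
#'
#' Density is proxied by the distance to the `rank`-th nearest neighbor in
#' diffusion space: the upper quartile of distances marks low-density cells,
#' the lower quartile high-density cells. Metacells containing such cells
#' inherit the stratum; each stratum is capped at 30% of metacells,
#' prioritized by how many stratum cells a metacell contains.
#'
#' @param dcs A `diffusion_embedding` or coordinate matrix.
#' @param assignment A `metacell_assignment` (or labels).
#' @param rank Neighbor rank used as the density proxy (default 150).
#' @param cap Stratum cap as a fraction of metacells (default 0.3).
#'
#' @return A list with `cells` (tibble: cell, rank_distance, stratum) and
#'   `metacells` (tibble: metacell, n_low, n_high, stratum).
#' @export
classify_density <- function(dcs, assignment, rank = 150, cap = 0.3) {
  coords <- if (inherits(dcs, "diffusion_embedding")) dcs$dcs else as.matrix(dcs)
  n <- nrow(coords)
  if (n <= rank) abort(sprintf("need more than %d cells for rank %d; reduce rank", rank, rank))
  labels <- if (inherits(assignment, "metacell_assignment")) assignment$labels else assignment
  nn <- RANN::nn2(coords, coords, k = rank + 1)
  d_rank <- nn$nn.dists[, rank + 1]
  stratum <- rep("mid", n)
  # ties at the cut included on the extreme side, then truncated to quartile size
  low_cand <- order(d_rank, decreasing = TRUE)[seq_len(floor(n / 4))]
  high_cand <- order(d_rank)[seq_len(floor(n / 4))]
  stratum[low_cand] <- "low"
  stratum[high_cand] <- "high"
  ids <- sort(unique(labels))
  n_low <- vapply(ids, function(m) sum(stratum[labels == m] == "low"), numeric(1))
  n_high <- vapply(ids, function(m) sum(stratum[labels == m] == "high"), numeric(1))
  max_mc <- ceiling(cap * length(ids))
  mc_stratum <- rep("mid", length(ids))
  low_order <- order(n_low, decreasing = TRUE)
  low_pick <- head(low_order[n_low[low_order] > 0], max_mc)
  mc_stratum[low_pick] <- "low"
  high_order <- order(n_high, decreasing = TRUE)
  high_order <- high_order[!(high_order %in% low_pick) & n_high[high_order] > 0]
  high_pick <- head(high_order, max_mc)
  mc_stratum[high_pick] <- "high"
  list(cells = tibble(cell = seq_len(n), rank_distance = d_rank, stratum = stratum),
       metacells = tibble(metacell = ids, n_low = as.integer(n_low),
                          n_high = as.integer(n_high), stratum = mc_stratum))
}

#' Shannon entropy of cell types in metacell neighborhoods
#'
#' For each metacell, the natural-log Shannon entropy of the cell-type
#' distribution over its `k` nearest metacell neighbors. High entropy means
#' well-mixed neighborhoods (for example after batch correction); 0 means a
#' homogeneous neighborhood.
#'
#' @param metacell_embedding Metacells x components coordinate matrix.
#' @param metacell_types Type label per metacell.
#' @param k Neighborhood size (default 10).
#' @return Tibble: `metacell`, `entropy`.
#' @export
neighborhood_entropy <- function(metacell_embedding, metacell_types, k = 10) {
  x <- as.matrix(metacell_embedding)
  n <- nrow(x)
  if (n <= k) abort("need more metacells than the neighborhood size k")
  nn <- RANN::nn2(x, x, k = k + 1)$nn.idx[, -1, drop = FALSE]
  ent <- vapply(seq_len(n), function(i) {
    p <- table(metacell_types[nn[i, ]]) / k
    -sum(p[p > 0] * log(p[p > 0]))
  }, numeric(1))
  tibble(metacell = seq_len(n), entropy = ent)
}
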