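#' Sample initialization waypoints
#'
#' Initialization cells for kernel archetypal analysis. A proportion of
#' waypoints is drawn by per-diffusion-component maximum-minimum sampling
#' (each new waypoint maximizes its minimum distance to the already chosen
#' set on that component); the pooled, de-duplicated picks are topped up to
#' `n_waypoints` by greedy column-subset selection on the kernel, which adds
#' at each step the column giving the largest reduction in Frobenius
#' reconstruction error of the kernel projected on the selected columns.
#'
#' @param dcs A `diffusion_embedding` (or a bare matrix of components).
#' @param kernel A `kernel_matrix` (used for the greedy fill).
#' @param n_waypoints Number of cells to return.
#' @param maxmin_proportion Fraction of waypoints taken by max-min sampling
#'   (default 1; the greedy selection then only fills the de-duplication
#'   shortfall).
#' @param seed Seed for the random first waypoint of each component.
#' @param init `"random"` starts each component's max-min chain at a random
#'   cell (seeded); `"extremal"` starts at the component's extremal cell,
#'   making the whole initialization deterministic.
#'
#' @return Integer vector of `n_waypoints` unique cell indices.
#' @export
sample_waypoints <- function(dcs, kernel, n_waypoints,
                             maxmin_proportion = 1, seed = 0,
                             init = c("random", "extremal")) {
  init <- match.arg(init)
  comps <- if (inherits(dcs, "diffusion_embedding")) dcs$dcs else as.matrix(dcs)
  n <- nrow(comps)
  if (n_waypoints > n) abort("n_waypoints cannot exceed the number of cells")
  if (n_waypoints < 1) abort("n_waypoints must be >= 1")
  if (maxmin_proportion < 0 || maxmin_proportion > 1) {
    abort("maxmin_proportion must lie in [0, 1]")
  }
  target <- ceiling(maxmin_proportion * n_waypoints)
  picked <- integer(0)
  if (target > 0) {
    ncomp <- ncol(comps)
    quota <- rep(ceiling(target / ncomp), ncomp)
    set.seed(derive_seed(seed, 11))
    starts <- if (init == "random") sample.int(n, ncomp, replace = TRUE)
              else apply(comps, 2, which.max)
    per_comp <- lapply(seq_len(ncomp), function(c) {
      maxmin_1d(comps[, c], quota[c], starts[c])
    })
    # interleave components so truncation keeps a balanced pool
    pool <- as.vector(t(matrix(unlist(lapply(per_comp, function(p) {
      length(p) <- max(lengths(per_comp)); p
    })), ncol = ncomp)))
    pool <- pool[!is.na(pool)]
    picked <- unique(pool)
    if (length(picked) > target) picked <- picked[seq_len(target)]
  }
  if (length(picked) < n_waypoints) {
    fill <- greedy_css(kernel$affinities, n_waypoints - length(picked), exclude = picked)
    picked <- c(picked, fill)
  }
  picked[seq_len(n_waypoints)]
}

# 1-D max-min chain: iteratively add the point farthest from the chosen set
maxmin_1d <- function(values, m, start) {
  n <- length(values)
  m <- min(m, n)
  sel <- integer(m)
  sel[1] <- start
  mind <- abs(values - values[start])
  if (m > 1) {
    for (t in 2:m) {
      nxt <- which.max(mind)    # which.max takes the lowest index on ties
      sel[t] <- nxt
      mind <- pmin(mind, abs(values - values[nxt]))
    }
  }
  sel
}

# greedy column subset selection: incremental Gram-Schmidt on kernel columns,
# maintaining squared residual norms of all columns
greedy_css <- function(m, n_pick, exclude = integer(0)) {
  if (n_pick <= 0) return(integer(0))
  n <- ncol(m)
  res2 <- Matrix::colSums(m^2)
  qbasis <- matrix(0, nrow(m), 0)
  chosen <- integer(0)
  # seed the projection with already-picked waypoints so fills complement them
  for (e in exclude) {
    q <- as.numeric(m[, e])
    if (ncol(qbasis)) q <- q - qbasis %*% crossprod(qbasis, q)
    nq <- sqrt(sum(q^2))
    if (nq > 1e-10) {
      q <- q / nq
      proj <- as.numeric(crossprod(m, q))
      res2 <- pmax(res2 - proj^2, 0)
      qbasis <- cbind(qbasis, q)
    }
  }
  avail <- setdiff(seq_len(n), exclude)
  for (t in seq_len(n_pick)) {
    cand <- avail[which.max(res2[avail])]
    chosen <- c(chosen, cand)
    avail <- setdiff(avail, cand)
    q <- as.numeric(m[, cand])
    if (ncol(qbasis)) q <- q - qbasis %*% crossprod(qbasis, q)
    nq <- sqrt(sum(q^2))
    if (nq > 1e-10) {
      q <- q / nq
      proj <- as.numeric(crossprod(m, q))
      res2 <- pmax(res2 - proj^2, 0)
      qbasis <- cbind(qbasis, q)
    }
  }
  chosen
}

#' Fit kernel archetypal analysis by alternating Frank-Wolfe updates
#'
#' Decomposes a symmetric cell-cell kernel `M` as `M ~ M B A` where the
#' archetype weight matrix `B` (n x s) and the membership matrix `A` (s x n)
#' are column-stochastic. The squared reconstruction error
#' `SRE = ||M - M B A||^2` is minimized by alternating convex block updates:
#' each outer iteration advances every column of one block by a Frank-Wolfe
#' step (vertex = most-negative gradient coordinate per column, then a single
#' exact line search on the quadratic objective, clipped to \[0, 1\]).
#' All SRE bookkeeping uses the trace identity, never densifying `M`.
#'
#' @param kernel A `kernel_matrix` or symmetric sparse matrix.
#' @param s Number of archetypes (metacells).
#' @param init Integer vector of `s` unique cell indices; `B` starts as
#'   indicator columns on these cells.
#' @param max_iter Maximum outer iterations (default 150).
#' @param tol Relative SRE decrease below which an iteration counts as
#'   converged; optimization stops after 3 consecutive such iterations and at
#'   least 10 iterations (default 1e-5).
#'
#' @return A `decomposition`: list with sparse `A` (s x n), `B` (n x s),
#'   `s`, `sre_trace` (non-increasing), `converged`, `n_iter`.
#' @export
fit_kernel_archetypes <- function(kernel, s, init, max_iter = 150, tol = 1e-5) {
  m <- if (inherits(kernel, "kernel_matrix")) kernel$affinities else kernel
  n <- nrow(m)
  if (s > n) abort("cannot fit more archetypes than cells")
  if (length(init) != s || anyDuplicated(init)) {
    abort("init must hold s unique cell indices")
  }
  if (max(abs(m - Matrix::t(m))) > 1e-8) abort("kernel must be symmetric")
  m <- as(as(m, "generalMatrix"), "CsparseMatrix")
  # B passes per outer iteration follow a per-iteration compute budget:
  # extra passes are nearly free on small problems and redundant on large
  # ones, where the per-column step sizes already move every archetype
  b_passes <- max(1L, min(4L, as.integer(round(4 * 2e6 / (n * s)))))
  res <- .fw_fit_cpp(m, as.integer(init) - 1L,
                     max_iter = max_iter, tol = tol, min_iter = 10L,
                     a_passes = 30L, b_passes = b_passes, init_a_passes = 40L)
  a <- sparseMatrix(i = res$ai, j = res$aj, x = res$ax, dims = c(s, n))
  b <- drop0(as(as(as(res$B, "dMatrix"), "generalMatrix"), "CsparseMatrix"))
  structure(list(A = a, B = b, s = s,
                 sre_trace = res$sre_trace,
                 converged = res$converged, n_iter = res$n_iter),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d archetypes over %d cells; SRE %.6g after %d iterations (%s)\n",
              x$s, ncol(x$A), tail(x$sre_trace, 1), x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

# column-wise argmin of a dense matrix
apply_colmin <- function(g) max.col(-t(g), ties.method = "first")

#' Squared reconstruction error of a kernel decomposition
#'
#' `SRE = ||M - M B A||_F^2`, evaluated through the trace identity
#' `tr(M'M) - 2 tr(A'C'M) + tr(A'H A)` with `C = M B`, `H = C'C`, so the
#' n x n reconstruction is never materialized.
#'
#' @param kernel A `kernel_matrix` or (sparse) symmetric matrix.
#' @param A s x n membership matrix.
#' @param B n x s archetype weight matrix.
#' @return Non-negative scalar.
#' @export
reconstruction_error <- function(kernel, A, B) {
  m <- if (inherits(kernel, "kernel_matrix")) kernel$affinities else kernel
  if (nrow(B) != nrow(m) || ncol(A) != ncol(m) || ncol(B) != nrow(A)) {
    abort(sprintf("shape mismatch: M %dx%d, B %dx%d, A %dx%d",
                  nrow(m), ncol(m), nrow(B), ncol(B), nrow(A), ncol(A)))
  }
  m <- as(as(m, "generalMatrix"), "CsparseMatrix")
  sre_trace_identity(m, A, B, sum(m@x^2))
}

sre_trace_identity <- function(m, a, b, normM2) {
  cc <- as.matrix(m %*% b)
  h <- crossprod(cc)
  cm <- as.matrix(Matrix::t(m %*% cc))        # C'M (s x n), using symmetry of M
  cross <- sum(a * cm)
  quad <- sum(as.matrix(h %*% a) * a)
  max(normM2 - 2 * cross + quad, 0)
}

#' Binarize archetype memberships into hard metacell assignments
#'
#' Zeroes per-cell weights below `trivial_threshold`, renormalizes the
#' remainder to sum to 1, and labels each cell by its maximal weight
#' (ties broken by the lowest metacell index). Cells whose weights are all
#' below the threshold keep their pre-threshold argmax, with a warning.
#'
#' @param decomposition A `decomposition` from [fit_kernel_archetypes()].
#' @param trivial_threshold Weights below this are zeroed (default 0.05).
#'
#' @return A `metacell_assignment`: list with `labels` (1-based metacell
#'   index per cell), `soft_weights` (sparse s x n renormalized), `max_weight`,
#'   `n_nontrivial`, `s`.
#' @export
hard_assignments <- function(decomposition, trivial_threshold = 0.05) {
  a <- as.matrix(decomposition$A)
  s <- nrow(a); n <- ncol(a)
  pre_arg <- apply_colmin(-a)
  keep <- a >= trivial_threshold
  aw <- a * keep
  csum <- colSums(aw)
  dead <- which(csum == 0)
  if (length(dead)) {
    warn(sprintf("%d cell(s) had all weights below %.3g; assigned by pre-threshold argmax",
                 length(dead), trivial_threshold))
    aw[cbind(pre_arg[dead], dead)] <- a[cbind(pre_arg[dead], dead)]
    csum <- colSums(aw)
  }
  aw <- sweep(aw, 2, csum, "/")
  labels <- apply_colmin(-aw)
  structure(list(labels = labels,
                 soft_weights = as(as(aw, "generalMatrix"), "CsparseMatrix"),
                 max_weight = aw[cbind(labels, seq_len(n))],
                 n_nontrivial = colSums(aw > 0),
                 s = s),
            class = "metacell_assignment")
}

#' @export
print.metacell_assignment <- function(x, ...) {
  cat(sprintf("<metacell_assignment> %d cells -> %d metacells (median size %d)\n",
              length(x$labels), length(unique(x$labels)),
              as.integer(median(table(x$labels)))))
  invisible(x)
}

#' Aggregate raw counts into metacell profiles
#'
#' Sums raw counts over the cells assigned to each metacell. Totals are
#' conserved exactly; empty metacells are dropped with a warning and the
#' remaining metacells re-indexed.
#'
#' @param counts A [cell_matrix()].
#' @param assignment A `metacell_assignment` covering all cells of `counts`.
#' @param celltypes Optional per-cell type labels; metacells then carry the
#'   modal type (lexicographic tie-break) and its frequency as purity.
#'
#' @return A `metacell_counts`: list with sparse `values` (s x features),
#'   `sizes`, `cell_ids` per metacell, and optional `celltype`/`purity`.
#' @export
aggregate_metacell_counts <- function(counts, assignment, celltypes = NULL) {
  stopifnot(is(counts, "cell_matrix"))
  labels <- assignment$labels
  n <- nrow(counts)
  if (length(labels) != n) abort("assignment does not cover all cells")
  s <- assignment$s
  if (any(labels < 1 | labels > s)) abort("metacell label out of range")
  present <- sort(unique(labels))
  if (length(present) < s) {
    warn(sprintf("%d empty metacell(s) dropped and re-indexed", s - length(present)))
  }
  newlab <- match(labels, present)
  ind <- sparseMatrix(i = newlab, j = seq_len(n), x = 1,
                      dims = c(length(present), n))
  vals <- ind %*% as_dgc(counts)
  rownames(vals) <- paste0("mc_", seq_along(present))
  colnames(vals) <- colnames(counts)
  out <- list(values = vals,
              sizes = as.integer(tabulate(newlab, length(present))),
              members = split(seq_len(n), newlab),
              original_index = present)
  if (!is.null(celltypes)) {
    ann <- vapply(out$members, function(ix) {
      tb <- sort(table(as.character(celltypes[ix])), decreasing = TRUE)
      top <- tb[tb == tb[1]]
      c(names(top)[order(names(top))][1], unname(tb[1]) / length(ix))
    }, character(2))
    out$celltype <- ann[1, ]
    out$purity <- as.numeric(ann[2, ])
  }
  structure(out, class = "metacell_counts")
}

#' @export
print.metacell_counts <- function(x, ...) {
  cat(sprintf("<metacell_counts> %d metacells x %d features (total %d counts)\n",
              nrow(x$values), ncol(x$values), as.integer(sum(x$values))))
  invisible(x)
}

#' Normalize aggregated metacell counts
#'
#' Divides each metacell by its total count, rescales by the median of the
#' metacell totals, and log-transforms with a pseudocount of 0.1:
#' `log(count / total * median_total + 0.1)`.
#'
#' @param mc A `metacell_counts` (or bare matrix, metacells in rows).
#' @return Dense s x features matrix of normalized log values.
#' @export
normalize_metacell_counts <- function(mc) {
  vals <- if (inherits(mc, "metacell_counts")) mc$values else mc
  totals <- Matrix::rowSums(vals)
  if (any(totals == 0)) abort("metacell(s) with zero total counts")
  scaled <- as.matrix(vals / totals * median(totals))
  log(scaled + 0.1)
}

#' Heuristic number of metacells
#'
#' One metacell per `cells_per_metacell` cells, rounded up. The default of
#' 75 suits typical datasets; rare-population protocols use the rare-state
#' cell count as the divisor instead.
#'
#' @param n_cells Number of cells.
#' @param cells_per_metacell Divisor (default 75).
#' @return Integer count.
#' @export
suggest_n_metacells <- function(n_cells, cells_per_metacell = 75) {
  if (n_cells < cells_per_metacell) {
    abort("n_cells must be at least cells_per_metacell")
  }
  as.integer(ceiling(n_cells / cells_per_metacell))
}

#' Summarize assignment confidence
#'
#' Histogram of per-cell maximal assignment weights over the bins
#' \[0, 0.5), \[0.5, 0.8), \[0.8, 0.9), \[0.9, 1\], plus the distribution of
#' the number of non-trivially assigned metacells per cell (a diagnostic for
#' a surplus of requested metacells).
#'
#' @param assignment A `metacell_assignment`.
#' @return A list with tibbles `weight_bins` (bin, n, fraction) and
#'   `n_nontrivial` (n_metacells, n_cells).
#' @export
summarize_assignment_confidence <- function(assignment) {
  w <- assignment$max_weight
  bins <- cut(w, breaks = c(0, 0.5, 0.8, 0.9, 1), right = FALSE,
              labels = c("[0,0.5)", "[0.5,0.8)", "[0.8,0.9)", "[0.9,1]"),
              include.lowest = TRUE)
  bins[w >= 0.9] <- "[0.9,1]"   # close the top bin at exactly 1
  tab <- table(bins)
  nn <- table(assignment$n_nontrivial)
  list(weight_bins = tibble(bin = names(tab), n = as.integer(tab),
                            fraction = as.integer(tab) / length(w)),
       n_nontrivial = tibble(n_metacells = as.integer(names(nn)),
                             n_cells = as.integer(nn)))
}
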