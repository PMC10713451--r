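#' Infer metacells from a raw count matrix
#'
#' End-to-end pipeline: normalization and embedding (PCA for RNA, TF-IDF/SVD
#' for ATAC), exact kNN graph, adaptive Gaussian kernel, diffusion map,
#' max-min + greedy column-subset initialization, kernel archetypal analysis
#' by alternating Frank-Wolfe updates, and binarized assignment.
#'
#' @param counts A [cell_matrix()], or a pre-computed `embedding` (skips the
#'   embedding step).
#' @param n_metacells Number of metacells; `NULL` applies the heuristic of
#'   one metacell per `cells_per_metacell` cells.
#' @param cells_per_metacell Heuristic divisor (default 75).
#' @param k Neighbors for the kNN graph (default 50, capped at n - 1).
#' @param l Bandwidth neighbor rank (default 15, capped at k - 1).
#' @param n_components Embedding dimensions (modality default when `NULL`).
#' @param n_hvg Highly variable genes for RNA (default 2500).
#' @param n_dcs Diffusion components for initialization (default 10).
#' @param trivial_threshold Assignment binarization threshold (default 0.05).
#' @param max_iter,tol Optimization controls, see [fit_kernel_archetypes()].
#' @param maxmin_proportion,waypoint_init See [sample_waypoints()].
#' @param seed Seed governing every random draw in the run.
#' @param celltypes Optional per-cell annotations, propagated to the
#'   aggregated metacells.
#'
#' @return A `metacell_fit` object bundling the embedding, kernel, diffusion
#'   map, decomposition, assignment and aggregated `metacell_counts`, with
#'   `tidy()`, `glance()` and `autoplot()` methods.
#' @export
metacells <- function(counts, n_metacells = NULL, cells_per_metacell = 75,
                      k = 50, l = 15, n_components = NULL, n_hvg = 2500,
                      n_dcs = 10, trivial_threshold = 0.05,
                      max_iter = 150, tol = 1e-5,
                      maxmin_proportion = 1, waypoint_init = "random",
                      seed = 0, celltypes = NULL) {
  if (inherits(counts, "embedding")) {
    emb <- counts
    counts <- NULL
  } else {
    stopifnot(is(counts, "cell_matrix"))
    emb <- compute_embedding(counts, modality = modality_of(counts),
                             n_components = n_components, n_hvg = n_hvg,
                             seed = seed)
  }
  n <- nrow(emb$coords)
  if (is.null(n_metacells)) n_metacells <- suggest_n_metacells(n, cells_per_metacell)
  k <- min(k, n - 1)
  l <- min(l, k - 1)
  graph <- build_knn_graph(emb, k = k)
  kernel <- compute_adaptive_kernel(graph, l = l)
  n_dcs_use <- min(n_dcs, n - 2)
  dmap <- diffusion_map(kernel, n_dcs = n_dcs_use, seed = seed)
  wp <- sample_waypoints(dmap, kernel, n_metacells,
                         maxmin_proportion = maxmin_proportion,
                         seed = seed, init = waypoint_init)
  dec <- fit_kernel_archetypes(kernel, s = n_metacells, init = wp,
                               max_iter = max_iter, tol = tol)
  asg <- hard_assignments(dec, trivial_threshold = trivial_threshold)
  mc <- if (!is.null(counts)) {
    aggregate_metacell_counts(counts, asg, celltypes = celltypes)
  }
  structure(list(embedding = emb, kernel = kernel, diffusion = dmap,
                 waypoints = wp, decomposition = dec, assignment = asg,
                 counts = mc,
                 params = list(n_metacells = n_metacells,
                               cells_per_metacell = cells_per_metacell,
                               k = k, l = l, n_dcs = n_dcs_use,
                               trivial_threshold = trivial_threshold,
                               max_iter = max_iter, tol = tol, seed = seed)),
            class = "metacell_fit")
}

#' @export
print.metacell_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("<metacell_fit> %d cells -> %d metacells ",
                     "(SRE %.5g, %d iterations, %s)\n"),
              g$n_cells, g$n_metacells, g$sre, g$n_iter,
              if (g$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Per-cell tidy summary of a metacell fit
#'
#' @param x A `metacell_fit`.
#' @param ... Unused.
#' @return A tibble with one row per cell: `cell`, `metacell`, `max_weight`,
#'   `n_nontrivial`.
#' @export
tidy.metacell_fit <- function(x, ...) {
  ids <- rownames(x$embedding$coords) %||% paste0("cell_", seq_along(x$assignment$labels))
  tibble(cell = ids,
         metacell = x$assignment$labels,
         max_weight = x$assignment$max_weight,
         n_nontrivial = as.integer(x$assignment$n_nontrivial))
}

#' One-row model summary of a metacell fit
#'
#' @param x A `metacell_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_cells`, `n_metacells`, `sre`, `n_iter`,
#'   `converged`, `median_max_weight`.
#' @export
glance.metacell_fit <- function(x, ...) {
  tibble(n_cells = length(x$assignment$labels),
         n_metacells = length(unique(x$assignment$labels)),
         sre = tail(x$decomposition$sre_trace, 1),
         n_iter = x$decomposition$n_iter,
         converged = x$decomposition$converged,
         median_max_weight = median(x$assignment$max_weight))
}

#' Plot a metacell fit
#'
#' Cells on the first two diffusion components, colored by metacell, with
#' metacell centroids overlaid.
#'
#' @param object A `metacell_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metacell_fit <- function(object, ...) {
  dc <- object$diffusion$dcs
  df <- tibble(dc1 = dc[, 1], dc2 = dc[, min(2, ncol(dc))],
               metacell = factor(object$assignment$labels))
  cent <- df |>
    dplyr::group_by(.data$metacell) |>
    dplyr::summarise(dc1 = mean(.data$dc1), dc2 = mean(.data$dc2))
  ggplot2::ggplot(df, ggplot2::aes(.data$dc1, .data$dc2, colour = .data$metacell)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_point(data = cent, shape = 21, size = 2.5, fill = "white",
                        show.legend = FALSE) +
    ggplot2::labs(x = "DC1", y = "DC2") +
    ggplot2::theme_minimal()
}

#' Plot the optimization trace of a metacell fit
#'
#' @param fit A `metacell_fit` or `decomposition`.
#' @return A ggplot object showing the (non-increasing) squared
#'   reconstruction error per iteration.
#' @export
plot_sre_trace <- function(fit) {
  dec <- if (inherits(fit, "metacell_fit")) fit$decomposition else fit
  df <- tibble(iteration = seq_along(dec$sre_trace) - 1, sre = dec$sre_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$sre)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(y = "squared reconstruction error") +
    ggplot2::theme_minimal()
}

#' Plot assignment-confidence bins
#'
#' @param assignment A `metacell_assignment` or `metacell_fit`.
#' @return A ggplot bar chart of the max-weight histogram over the bins
#'   \[0, 0.5), \[0.5, 0.8), \[0.8, 0.9), \[0.9, 1\].
#' @export
plot_assignment_confidence <- function(assignment) {
  if (inherits(assignment, "metacell_fit")) assignment <- assignment$assignment
  s <- summarize_assignment_confidence(assignment)
  ggplot2::ggplot(s$weight_bins,
                  ggplot2::aes(.data$bin, .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "maximal assignment weight", y = "fraction of cells") +
    ggplot2::theme_minimal()
}
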