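#' Run per-sample metacell inference over a cohort
#'
#' Applies [metacells()] independently to each sample of a cohort and
#' aggregates per-sample raw counts, tagging every metacell with its sample
#' and condition.
#'
#' @param samples Named list of [cell_matrix()] objects (one per sample).
#' @param manifest Tibble with `sample_id` and `condition` (extra columns
#'   such as site or days since onset are carried along).
#' @param celltypes Optional named list of per-cell type labels.
#' @param cells_per_metacell Heuristic divisor (default 75).
#' @param seed Seed; each sample derives its own stream.
#' @param ... Further arguments to [metacells()].
#'
#' @return A `cohort_assignment`: list with `fits` (per-sample
#'   `metacell_fit`), `metacells` (tibble: metacell_id, sample_id, condition,
#'   size, celltype, purity), `expression` (pooled metacells x genes raw
#'   counts), `manifest`.
#' @export
cohort_metacells <- function(samples, manifest, celltypes = NULL,
                             cells_per_metacell = 75, seed = 0, ...) {
  stopifnot(all(manifest$sample_id %in% names(samples)))
  fits <- list(); rows <- list(); mats <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    ct <- if (!is.null(celltypes)) celltypes[[sid]]
    fit <- metacells(samples[[sid]], cells_per_metacell = cells_per_metacell,
                     seed = derive_seed(seed, i), celltypes = ct, ...)
    fits[[sid]] <- fit
    mc <- fit$counts
    ids <- sprintf("%s_mc_%03d", sid, seq_len(nrow(mc$values)))
    rownames(mc$values) <- ids
    rows[[sid]] <- tibble(metacell_id = ids, sample_id = sid,
                          condition = manifest$condition[i],
                          size = mc$sizes,
                          celltype = mc$celltype %||% NA_character_,
                          purity = mc$purity %||% NA_real_)
    mats[[sid]] <- mc$values
  }
  genes <- Reduce(intersect, lapply(mats, colnames))
  pooled <- do.call(rbind, lapply(mats, function(m) m[, genes, drop = FALSE]))
  structure(list(fits = fits, metacells = dplyr::bind_rows(rows),
                 expression = pooled, manifest = manifest),
            class = "cohort_assignment")
}

#' @export
print.cohort_assignment <- function(x, ...) {
  cat(sprintf("<cohort_assignment> %d samples, %d metacells, %d shared genes\n",
              length(x$fits), nrow(x$metacells), ncol(x$expression)))
  invisible(x)
}

#' Map metacells between samples by mutual nearest neighbors
#'
#' Computes diffusion components from the supplied (batch-corrected)
#' metacell embedding, then declares two metacells from different samples
#' equivalent when each is among the other's top two nearest cross-sample
#' neighbors. When types are supplied, reports the fraction of equivalent
#' pairs with matching type.
#'
#' @param embedding Metacells x components matrix (already batch-corrected;
#'   this function never corrects internally).
#' @param sample_ids Sample label per metacell row.
#' @param n_dcs Diffusion components to use (default 10).
#' @param types Optional type label per metacell.
#' @param top Mutual-neighbor depth (default 2).
#' @param seed Seed for the eigensolver.
#'
#' @return A list with `pairs` (tibble: sample_a, metacell_a, sample_b,
#'   metacell_b, matched_type) — each unordered pair reported once — and
#'   `matched_fraction`.
#' @export
map_metacells_between_samples <- function(embedding, sample_ids, n_dcs = 10,
                                          types = NULL, top = 2, seed = 0) {
  x <- as.matrix(embedding)
  sample_ids <- as.character(sample_ids)
  tab <- table(sample_ids)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warn(sprintf("sample(s) with < 3 metacells excluded: %s",
                 paste(small, collapse = ", ")))
    keep <- !(sample_ids %in% small)
    x <- x[keep, , drop = FALSE]
    sample_ids <- sample_ids[keep]
    if (!is.null(types)) types <- types[keep]
  }
  if (length(unique(sample_ids)) < 2) abort("need at least 2 samples")
  dcs <- embedding_dcs(x, n_dcs, seed)
  samples <- unique(sample_ids)
  pairs <- list()
  for (a_i in seq_along(samples)) for (b_i in seq_along(samples)) {
    if (b_i <= a_i) next
    ia <- which(sample_ids == samples[a_i])
    ib <- which(sample_ids == samples[b_i])
    ka <- min(top, length(ib)); kb <- min(top, length(ia))
    nn_ab <- RANN::nn2(dcs[ib, , drop = FALSE], dcs[ia, , drop = FALSE], k = ka)$nn.idx
    nn_ba <- RANN::nn2(dcs[ia, , drop = FALSE], dcs[ib, , drop = FALSE], k = kb)$nn.idx
    for (q in seq_along(ia)) {
      for (j in nn_ab[q, ]) {
        if (q %in% nn_ba[j, ]) {
          pairs[[length(pairs) + 1]] <- tibble(
            sample_a = samples[a_i], metacell_a = ia[q],
            sample_b = samples[b_i], metacell_b = ib[j],
            matched_type = if (!is.null(types)) {
              as.character(types[ia[q]]) == as.character(types[ib[j]])
            } else NA)
        }
      }
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  list(pairs = pairs,
       matched_fraction = if (!is.null(types) && nrow(pairs)) {
         mean(pairs$matched_type)
       } else NA_real_)
}

# diffusion components of an arbitrary point set (kNN + adaptive kernel)
embedding_dcs <- function(x, n_dcs, seed = 0) {
  n <- nrow(x)
  k <- min(50, n - 1)
  graph <- build_knn_graph(x, k = k)
  kern <- compute_adaptive_kernel(graph, l = max(1, min(15, k - 1)))
  diffusion_map(kern, n_dcs = min(n_dcs, n - 2), seed = seed)$dcs
}

#' Aggregate cohort metacells into meta2cells
#'
#' Re-runs the kernel archetypal pipeline on the pooled metacell embedding
#' with approximately one meta2cell per `ratio` metacells, then summarizes
#' each meta2cell's condition composition and annotates it with the modal
#' cell type when the (size-weighted) purity exceeds `purity_threshold`,
#' otherwise `"Mixed"`.
#'
#' @param embedding Pooled, batch-corrected metacells x components matrix.
#' @param metacell_info Tibble with one row per metacell: `condition`, and
#'   optionally `celltype` and `size` (size defaults to 1).
#' @param ratio Metacells per meta2cell (default 10).
#' @param purity_threshold Annotation purity cut (default 0.8).
#' @param disease_condition Condition whose proportion is reported; defaults
#'   to the last condition level.
#' @param seed Seed.
#'
#' @return A `meta2_assignment`: list with `labels` (metacell ->
#'   meta2cell), `summary` tibble (meta2cell, n_metacells, proportion,
#'   annotation, purity), `fit` (the underlying `metacell_fit`),
#'   `disease_condition`.
#' @export
build_meta2cells <- function(embedding, metacell_info, ratio = 10,
                             purity_threshold = 0.8,
                             disease_condition = NULL, seed = 0) {
  x <- as.matrix(embedding)
  n <- nrow(x)
  stopifnot(nrow(metacell_info) == n)
  conds <- unique(as.character(metacell_info$condition))
  if (length(conds) < 2) {
    warn("single condition: proportions computed, the abundance test will be disabled")
  }
  disease_condition <- disease_condition %||% conds[length(conds)]
  s <- max(2, ceiling(n / ratio))
  emb <- structure(list(coords = x, n_components = ncol(x), modality = "rna",
                        component_variances = apply(x, 2, var)),
                   class = "embedding")
  fit <- metacells(emb, n_metacells = s, seed = seed)
  labels <- fit$assignment$labels
  sizes <- metacell_info$size %||% rep(1, n)
  is_disease <- as.character(metacell_info$condition) == disease_condition
  ids <- sort(unique(labels))
  summ <- lapply(ids, function(m) {
    ix <- which(labels == m)
    prop <- mean(is_disease[ix])
    ann <- NA_character_; pur <- NA_real_
    if (!is.null(metacell_info$celltype)) {
      w <- tapply(sizes[ix], metacell_info$celltype[ix], sum)
      pur <- max(w) / sum(w)
      ann <- if (pur > purity_threshold) names(w)[which.max(w)] else "Mixed"
    }
    tibble(meta2cell = m, n_metacells = length(ix), proportion = prop,
           annotation = ann, purity = pur)
  })
  structure(list(labels = labels, summary = dplyr::bind_rows(summ), fit = fit,
                 disease_condition = disease_condition,
                 conditions = as.character(metacell_info$condition)),
            class = "meta2_assignment")
}

#' @export
print.meta2_assignment <- function(x, ...) {
  cat(sprintf("<meta2_assignment> %d metacells -> %d meta2cells\n",
              length(x$labels), nrow(x$summary)))
  invisible(x)
}

#' Permutation test for condition enrichment of meta2cells
#'
#' Permutes the metacell-to-meta2cell assignment (meta2cell sizes fixed,
#' condition labels riding along) to build a null distribution of the
#' disease proportion per meta2cell, then reports the add-one empirical
#' p-value. Two-sided by default (`min(lower, upper) * 2`, capped at 1), so
#' both enriched and depleted states are flagged.
#'
#' @param meta2 A `meta2_assignment` from [build_meta2cells()].
#' @param n_permutations Permutation trials (default 5000; at least 100).
#' @param alpha Significance threshold (default 0.1).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param seed Seed; results are fully seed-deterministic.
#'
#' @return Tibble: `meta2cell`, `n_metacells`, `proportion`, `p`,
#'   `significant`.
#' @export
test_differential_abundance <- function(meta2, n_permutations = 5000,
                                        alpha = 0.1,
                                        alternative = c("two.sided", "greater"),
                                        seed = 0) {
  alternative <- match.arg(alternative)
  if (n_permutations < 100) abort("use at least 100 permutations")
  labels <- meta2$labels
  is_disease <- meta2$conditions == meta2$disease_condition
  if (all(is_disease) || !any(is_disease)) {
    out <- meta2$summary["meta2cell"]
    out$n_metacells <- meta2$summary$n_metacells
    out$proportion <- meta2$summary$proportion
    out$p <- 1; out$significant <- FALSE
    return(out)
  }
  ids <- sort(unique(labels))
  s <- length(ids)
  lab_f <- match(labels, ids)
  sizes <- tabulate(lab_f, s)
  obs <- rowsum(as.numeric(is_disease), lab_f)[, 1] / sizes
  set.seed(derive_seed(seed, 501))
  ge <- integer(s); le <- integer(s)
  n <- length(labels)
  # permuting assignments with sizes fixed == permuting the condition labels
  for (b in seq_len(n_permutations)) {
    prop <- rowsum(as.numeric(is_disease[sample.int(n)]), lab_f)[, 1] / sizes
    ge <- ge + (prop >= obs - 1e-12)
    le <- le + (prop <= obs + 1e-12)
  }
  p_up <- (1 + ge) / (1 + n_permutations)
  p_dn <- (1 + le) / (1 + n_permutations)
  p <- if (alternative == "greater") p_up else pmin(1, 2 * pmin(p_up, p_dn))
  tibble(meta2cell = ids, n_metacells = as.integer(sizes),
         proportion = obs, p = p, significant = p < alpha)
}
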