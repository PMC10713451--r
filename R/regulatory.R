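#' Fit smoothed gene expression trends along a pseudotime
#'
#' Per gene, fits an additive model `y = b0 + f(tau)` with a cubic-regression
#' -spline smoother by penalized least squares, then z-scores the fitted
#' values across the lineage metacells. Constant genes return all-zero
#' trends.
#'
#' @param expr Metacells x genes matrix of (normalized) expression.
#' @param pseudotime Numeric pseudotime per metacell.
#' @param lineage Optional metacell subset (indices or row names) defining
#'   the lineage; default all.
#' @param basis_dim Spline basis dimension (default 6), reduced with a
#'   warning when the lineage has too few metacells.
#'
#' @return A list with `trends` (genes x lineage-metacells z-scored fitted
#'   values), `fitted` (unscaled), `pseudotime`, `metacells`.
#' @export
fit_gene_trends <- function(expr, pseudotime, lineage = NULL, basis_dim = 6) {
  if (is.null(lineage)) lineage <- seq_len(nrow(expr))
  if (is.character(lineage)) lineage <- match(lineage, rownames(expr))
  if (!length(lineage)) abort("lineage subset is empty")
  if (length(lineage) < 8) abort("need at least 8 metacells on the lineage")
  tau <- pseudotime[lineage]
  if (any(!is.finite(tau))) abort("pseudotime must be finite")
  y <- expr[lineage, , drop = FALSE]
  k <- basis_dim
  if (k >= length(lineage)) {
    k <- max(3, length(lineage) - 2)
    warn(sprintf("spline basis reduced to %d for %d metacells", k, length(lineage)))
  }
  n_genes <- ncol(y)
  fitted <- matrix(0, n_genes, length(lineage),
                   dimnames = list(colnames(y), rownames(expr)[lineage]))
  df <- data.frame(tau = tau)
  for (g in seq_len(n_genes)) {
    yy <- y[, g]
    if (sd(yy) == 0) next
    df$y <- yy
    fit <- mgcv::gam(y ~ s(tau, bs = "cr", k = k), data = df)
    fitted[g, ] <- fitted(fit)
  }
  trends <- t(apply(fitted, 1, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(trends) <- dimnames(fitted)
  list(trends = trends, fitted = fitted, pseudotime = tau,
       metacells = rownames(expr)[lineage])
}

#' Build the TF-target matrix from links and motif scores
#'
#' For gene g, the qualifying peak set `S_g` holds peaks whose accessibility
#' correlates with g's expression (empirical `p < p_threshold`, correlation
#' `r > r_threshold`). The TF weight is the correlation-weighted mean of
#' motif scores over `S_g`:
#' `G_gt = sum_k c_kg * F_kt / sum_k c_kg`, k in S_g.
#' Genes with empty `S_g` get zero rows.
#'
#' @param links Link tibble from [correlate_peaks_genes()].
#' @param motif_scores Peaks x TFs numeric matrix of motif scores (or a long
#'   tibble with `peak`, `tf`, `score`).
#' @param p_threshold,r_threshold Qualification cuts (defaults 0.1 and 0.1).
#'
#' @return A list with `G` (genes x TFs), `peak_sets` (qualifying peaks per
#'   gene).
#' @export
build_tf_target_matrix <- function(links, motif_scores,
                                   p_threshold = 0.1, r_threshold = 0.1) {
  if (is.data.frame(motif_scores)) {
    motif_scores <- long_to_matrix(motif_scores, "peak", "tf", "score")
  }
  qual <- links[links$p < p_threshold & links$r > r_threshold, , drop = FALSE]
  genes <- unique(links$gene)
  tfs <- colnames(motif_scores)
  g_mat <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  sets <- split(seq_len(nrow(qual)), qual$gene)
  for (g in names(sets)) {
    rows <- sets[[g]]
    pk <- qual$peak[rows]
    pk_in <- pk %in% rownames(motif_scores)
    if (!any(pk_in)) next
    c_kg <- qual$r[rows][pk_in]
    f <- motif_scores[pk[pk_in], , drop = FALSE]
    g_mat[g, ] <- colSums(f * c_kg) / sum(c_kg)
  }
  list(G = g_mat, peak_sets = lapply(sets, function(r) qual$peak[r]))
}

long_to_matrix <- function(df, row, col, val) {
  rn <- sort(unique(df[[row]])); cn <- sort(unique(df[[col]]))
  m <- matrix(0, length(rn), length(cn), dimnames = list(rn, cn))
  m[cbind(match(df[[row]], rn), match(df[[col]], cn))] <- df[[val]]
  m
}

#' Infer TF activities by lasso regression with signed leave-one-out error
#'
#' For each metacell, fits a lasso of the metacell's gene trend on the
#' (column-standardized) TF-target matrix, choosing the penalty by 10-fold
#' cross-validation. The activity of TF t is the increase in squared
#' prediction error when t's term is dropped from the fitted predictor,
#' signed by its coefficient:
#' `activity = (SSE_without_t - SSE_full) * sign(w_t)`, and 0 when `w_t = 0`.
#' TFs are ranked by their total (signed) activity across metacells.
#'
#' @param tf_target A result of [build_tf_target_matrix()] (or bare genes x
#'   TFs matrix).
#' @param trends Genes x metacells matrix (z-scored trends from
#'   [fit_gene_trends()]).
#' @param n_folds Cross-validation folds (default 10; reduced with a warning
#'   when genes are scarce).
#' @param rank_by `"signed"` (default) sums signed activities; `"absolute"`
#'   sums absolute activities.
#' @param seed Seed for fold shuffling.
#'
#' @return A `tf_activity` list: `activities` (TFs x metacells),
#'   `coefficients` (TFs x metacells), `lambda` per metacell, `ranking`
#'   tibble (tf, total_activity).
#' @export
infer_tf_activities <- function(tf_target, trends, n_folds = 10,
                                rank_by = c("signed", "absolute"), seed = 0) {
  rank_by <- match.arg(rank_by)
  g_mat <- if (is.list(tf_target)) tf_target$G else tf_target
  shared <- intersect(rownames(g_mat), rownames(trends))
  if (length(shared) < 3) abort("too few genes shared between G and trends")
  g_mat <- g_mat[shared, , drop = FALSE]
  trends <- trends[shared, , drop = FALSE]
  keep_tf <- colSums(abs(g_mat)) > 0
  if (sum(keep_tf) < 2) abort("need at least 2 TFs with non-zero columns")
  g_mat <- g_mat[, keep_tf, drop = FALSE]
  x <- scale(g_mat)
  x[, attr(x, "scaled:scale") == 0] <- 0
  n_genes <- nrow(x)
  if (n_genes < n_folds) {
    n_folds <- max(3, n_genes %/% 2)
    warn(sprintf("folds reduced to %d for %d genes", n_folds, n_genes))
  }
  s <- ncol(trends)
  tfs <- colnames(g_mat)
  acts <- matrix(0, length(tfs), s, dimnames = list(tfs, colnames(trends)))
  coefs <- acts
  lambdas <- numeric(s)
  intercepts <- numeric(s)
  set.seed(derive_seed(seed, 401))
  foldid <- sample(rep(seq_len(n_folds), length.out = n_genes))
  for (m in seq_len(s)) {
    y <- trends[, m]
    cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                            standardize = FALSE)
    lambdas[m] <- cv$lambda.min
    w <- as.numeric(coef(cv, s = "lambda.min"))[-1]
    b0 <- as.numeric(coef(cv, s = "lambda.min"))[1]
    pred <- as.numeric(x %*% w) + b0
    sse_full <- sum((y - pred)^2)
    nz <- which(w != 0)
    for (t in nz) {
      pred_t <- pred - x[, t] * w[t]
      acts[t, m] <- (sum((y - pred_t)^2) - sse_full) * sign(w[t])
    }
    coefs[, m] <- w
    intercepts[m] <- b0
  }
  total <- if (rank_by == "signed") rowSums(acts) else rowSums(abs(acts))
  ranking <- tibble(tf = tfs, total_activity = total) |>
    dplyr::arrange(dplyr::desc(.data$total_activity))
  structure(list(activities = acts, coefficients = coefs,
                 lambda = lambdas, intercepts = intercepts,
                 ranking = ranking, rank_by = rank_by),
            class = "tf_activity")
}

#' @export
print.tf_activity <- function(x, ...) {
  cat(sprintf("<tf_activity> %d TFs x %d metacells; top: %s\n",
              nrow(x$activities), ncol(x$activities), x$ranking$tf[1]))
  invisible(x)
}

#' Tidy TF activities
#'
#' @param x A `tf_activity`.
#' @param ... Unused.
#' @return Long tibble: `tf`, `metacell`, `activity`, `coefficient`.
#' @export
tidy.tf_activity <- function(x, ...) {
  mc <- colnames(x$activities) %||% paste0("mc_", seq_len(ncol(x$activities)))
  tibble(tf = rep(rownames(x$activities), times = ncol(x$activities)),
         metacell = rep(mc, each = nrow(x$activities)),
         activity = as.vector(x$activities),
         coefficient = as.vector(x$coefficients))
}

#' Rank-sum differential expression helper
#'
#' Wilcoxon rank-sum test of each gene between two groups of metacells, with
#' Benjamini-Hochberg adjustment. A convenience for selecting trend genes and
#' annotating meta2cell signatures.
#'
#' @param expr Metacells x genes matrix (normalized).
#' @param group Logical or two-level factor over metacells.
#' @return Tibble: `gene`, `stat`, `p`, `p_adj`, `log_fc` (difference of
#'   group means on the log scale).
#' @export
rank_sum_de <- function(expr, group) {
  grp <- as.factor(group)
  if (nlevels(grp) != 2) abort("group must have exactly two levels")
  a <- expr[grp == levels(grp)[1], , drop = FALSE]
  b <- expr[grp == levels(grp)[2], , drop = FALSE]
  res <- apply(expr, 2, function(v) {
    wt <- suppressWarnings(stats::wilcox.test(v[grp == levels(grp)[1]],
                                              v[grp == levels(grp)[2]]))
    c(wt$statistic, wt$p.value)
  })
  tibble(gene = colnames(expr), stat = res[1, ], p = res[2, ],
         p_adj = stats::p.adjust(res[2, ], "BH"),
         log_fc = colMeans(a) - colMeans(b))
}
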