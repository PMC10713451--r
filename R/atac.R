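#' Keep nucleosome-free-region (NFR) fragments
#'
#' Retains fragments strictly shorter than `max_length_exclusive` bases
#' (default 147, one nucleosomal wrap); such fragments are enriched for
#' TF-bound open chromatin and give more sensitive peak signal.
#'
#' @param fragments Tibble with `chrom`, `start`, `end`, `barcode` and
#'   optional `count` (0-based half-open coordinates).
#' @param max_length_exclusive Length bound, exclusive (default 147).
#'
#' @return The retained fragments, with attribute `retained_fraction`.
#' @export
filter_nfr_fragments <- function(fragments, max_length_exclusive = 147) {
  check_fragments(fragments)
  len <- fragments$end - fragments$start
  out <- fragments[len < max_length_exclusive, , drop = FALSE]
  attr(out, "retained_fraction") <-
    if (nrow(fragments)) nrow(out) / nrow(fragments) else NA_real_
  out
}

check_fragments <- function(fragments) {
  stopifnot(all(c("chrom", "start", "end", "barcode") %in% names(fragments)))
  bad <- which(fragments$end <= fragments$start)
  if (length(bad)) {
    abort(sprintf("malformed fragment record(s): end <= start at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  invisible(fragments)
}

#' Count fragments in peaks per metacell
#'
#' A fragment contributes to a peak when either of its Tn5 insertion sites
#' (`start`, or `end - 1`) lies within the peak; a fragment is counted at
#' most once per peak. Barcodes are mapped to metacells via the assignment;
#' unassigned barcodes are dropped and reported. With `augment = TRUE`, each
#' metacell's per-peak counts and total are pooled with its two nearest
#' metacells (centroid Euclidean distance in the supplied diffusion
#' embedding), which stabilizes low-count metacells.
#'
#' @param fragments Fragment tibble (see [filter_nfr_fragments()]).
#' @param peaks Peak tibble with `peak`, `chrom`, `start`, `end`.
#' @param barcodes Character vector of cell barcodes, in assignment order.
#' @param assignment A `metacell_assignment` over those barcodes.
#' @param augment Pool with the two nearest metacells (default FALSE).
#' @param dcs Metacell-resolvable diffusion embedding (cells x components)
#'   used to place metacell centroids; required when `augment = TRUE`.
#'
#' @return A list with sparse `counts` (s x peaks), `totals` (per-metacell
#'   total fragment counts, in-peak and genome-wide alike pooled when
#'   augmented), `n_unassigned` barcode records dropped.
#' @export
count_peak_fragments <- function(fragments, peaks, barcodes, assignment,
                                 augment = FALSE, dcs = NULL) {
  check_fragments(fragments)
  s <- assignment$s
  lab <- setNames(assignment$labels, barcodes)
  mc <- lab[fragments$barcode]
  unassigned <- sum(is.na(mc))
  if (unassigned) {
    inform(sprintf("%d fragment record(s) with unassigned barcodes dropped", unassigned))
  }
  frg <- fragments[!is.na(mc), , drop = FALSE]
  mc <- mc[!is.na(mc)]
  cnt <- if ("count" %in% names(frg)) frg$count else rep(1L, nrow(frg))
  missing_chr <- setdiff(unique(frg$chrom), unique(peaks$chrom))
  if (length(missing_chr)) {
    warn(sprintf("chromosome(s) %s absent from the peak set; fragments skipped",
                 paste(missing_chr, collapse = ", ")))
  }
  totals <- as.numeric(tapply(cnt, factor(mc, levels = seq_len(s)), sum,
                              default = 0))
  ij <- list()
  for (chr in intersect(unique(frg$chrom), unique(peaks$chrom))) {
    fi <- which(frg$chrom == chr)
    pi <- which(peaks$chrom == chr)
    pr <- IRanges::IRanges(start = peaks$start[pi] + 1, end = peaks$end[pi])
    # Tn5 insertion sites of the fragment, as width-1 ranges (1-based)
    left <- IRanges::IRanges(start = frg$start[fi] + 1, width = 1)
    right <- IRanges::IRanges(start = frg$end[fi], width = 1)
    ovl <- unique(rbind(
      as.matrix(IRanges::findOverlaps(left, pr)),
      as.matrix(IRanges::findOverlaps(right, pr))))
    if (nrow(ovl)) {
      ij[[chr]] <- data.frame(mc = mc[fi[ovl[, 1]]],
                              peak = pi[ovl[, 2]],
                              n = cnt[fi[ovl[, 1]]])
    }
  }
  ij <- do.call(rbind, ij)
  counts <- if (is.null(ij) || !nrow(ij)) {
    sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                 dims = c(s, nrow(peaks)))
  } else {
    sparseMatrix(i = ij$mc, j = ij$peak, x = ij$n,
                 dims = c(s, nrow(peaks)))
  }
  if (augment) {
    if (is.null(dcs)) abort("augment = TRUE needs the diffusion embedding (dcs)")
    coords <- if (inherits(dcs, "diffusion_embedding")) dcs$dcs else as.matrix(dcs)
    cent <- centroid_matrix(coords, assignment$labels, s)
    nn <- nearest_neighbors(cent, 2)
    pool <- sparseMatrix(i = rep(seq_len(s), 3),
                         j = c(seq_len(s), nn[, 1], nn[, 2]),
                         x = 1, dims = c(s, s))
    counts <- pool %*% counts
    totals <- as.numeric(pool %*% totals)
  }
  rownames(counts) <- paste0("mc_", seq_len(s))
  colnames(counts) <- peaks$peak
  list(counts = counts, totals = totals, n_unassigned = unassigned)
}

centroid_matrix <- function(coords, labels, s) {
  ind <- sparseMatrix(i = labels, j = seq_along(labels), x = 1,
                      dims = c(s, length(labels)))
  as.matrix((ind %*% coords) / pmax(Matrix::rowSums(ind), 1))
}

nearest_neighbors <- function(x, k) {
  nn <- RANN::nn2(x, x, k = min(k + 1, nrow(x)))
  nn$nn.idx[, -1, drop = FALSE]
}

#' Call open peaks per metacell with a Poisson background
#'
#' Models in-peak fragment counts as Poisson. The per-metacell rate is
#' `lambda = peak_width * total_fragments / (n_peaks * eff_length_multiplier)`
#' (a local effective-genome-length background in the MACS lineage); the
#' per-peak p-value is the upper tail `P(X > n)` and a peak is called open
#' when `p < p_threshold`.
#'
#' @param counts s x peaks fragment counts (from [count_peak_fragments()],
#'   or a bare matrix).
#' @param totals Per-metacell total fragment counts; taken from `counts` when
#'   it is a `count_peak_fragments()` result.
#' @param peak_width Common peak width in bases (default 500).
#' @param eff_length_multiplier Effective-genome-length multiplier per peak
#'   (default 5000).
#' @param p_threshold Open-call threshold (default 0.01).
#'
#' @return An `open_peaks` list: binary sparse `open` (s x peaks), dense
#'   `p_values`, per-metacell `lambda`.
#' @export
call_open_peaks <- function(counts, totals = NULL, peak_width = 500,
                            eff_length_multiplier = 5000, p_threshold = 0.01) {
  if (is.list(counts) && !is.null(counts$counts)) {
    totals <- totals %||% counts$totals
    counts <- counts$counts
  }
  if (is.null(totals)) totals <- Matrix::rowSums(counts)
  s <- nrow(counts); n_peaks <- ncol(counts)
  lambda <- peak_width * totals / (n_peaks * eff_length_multiplier)
  if (any(lambda == 0)) warn("metacell(s) with zero total fragments: all peaks closed")
  cm <- as.matrix(counts)
  p <- matrix(1, s, n_peaks, dimnames = dimnames(cm))
  for (m in seq_len(s)) {
    if (lambda[m] > 0) p[m, ] <- ppois(cm[m, ], lambda[m], lower.tail = FALSE)
  }
  open <- (p < p_threshold) & lambda > 0
  structure(list(open = as(as(open * 1, "generalMatrix"), "CsparseMatrix"),
                 p_values = p, lambda = lambda,
                 p_threshold = p_threshold),
            class = "open_peaks")
}

#' Associate peaks with genes by matched-background correlation
#'
#' For each gene, candidate peaks lie within `window_kb` of the gene body.
#' The observed statistic is the Pearson (optionally Spearman) correlation
#' between normalized metacell accessibility of the peak and normalized
#' metacell expression of the gene. Significance is assessed against an
#' empirical background of `n_background` peaks drawn from the candidate
#' peak's joint (GC content x total accessibility) bin — equal-frequency
#' quantile bins, sampling with replacement when a bin is small — using the
#' one-sided add-one estimator `p = (1 + #{r_bg >= r}) / (1 + n_background)`.
#'
#' @param mc_expr Normalized metacells x genes matrix
#'   ([normalize_metacell_counts()] of the RNA aggregate).
#' @param mc_acc Normalized metacells x peaks matrix (ATAC aggregate), rows
#'   aligned with `mc_expr`.
#' @param genes Gene tibble with `gene`, `chrom`, `start`, `end`.
#' @param peaks Peak tibble with `peak`, `chrom`, `start`, `end`, `gc`.
#' @param window_kb Candidate window around the gene body (default 100).
#' @param n_background Background draws per link (default 100).
#' @param n_bins Quantile bins per matching covariate (default 100; use
#'   fewer for small peak sets so bins stay populated).
#' @param p_threshold Significance call (default 0.1).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param seed Seed for background sampling.
#'
#' @return A tibble of links: `gene`, `peak`, `r`, `p`, `significant`,
#'   `distance` (gene-body gap in bp); excluded zero-variance pairs carry
#'   attribute `excluded`.
#' @export
correlate_peaks_genes <- function(mc_expr, mc_acc, genes, peaks,
                                  window_kb = 100, n_background = 100,
                                  n_bins = 100, p_threshold = 0.1,
                                  method = c("pearson", "spearman"), seed = 0) {
  method <- match.arg(method)
  stopifnot(nrow(mc_expr) == nrow(mc_acc))
  if (!all(peaks$peak %in% colnames(mc_acc))) abort("peaks missing from mc_acc columns")
  if (is.null(peaks$gc)) abort("peaks need a gc column for background matching")
  set.seed(derive_seed(seed, 301))
  if (method == "spearman") {
    mc_expr <- apply(mc_expr, 2, rank)
    mc_acc <- apply(mc_acc, 2, rank)
  }
  acc_tot <- Matrix::colSums(mc_acc[, peaks$peak, drop = FALSE])
  bin_gc <- quantile_bin(peaks$gc, n_bins)
  bin_acc <- quantile_bin(acc_tot, n_bins)
  joint <- paste(bin_gc, bin_acc)
  bin_members <- split(seq_len(nrow(peaks)), joint)
  genes_use <- genes[genes$gene %in% colnames(mc_expr), , drop = FALSE]
  window <- window_kb * 1000
  links <- list(); excluded <- list()
  acc_mat <- as.matrix(mc_acc[, peaks$peak, drop = FALSE])
  acc_ctr <- scale(acc_mat, center = TRUE, scale = FALSE)
  acc_sd <- sqrt(colSums(acc_ctr^2))
  for (gi in seq_len(nrow(genes_use))) {
    g <- genes_use$gene[gi]
    cand <- which(peaks$chrom == genes_use$chrom[gi] &
                    peaks$end > genes_use$start[gi] - window &
                    peaks$start < genes_use$end[gi] + window)
    if (!length(cand)) next
    y <- mc_expr[, g]
    yc <- y - mean(y)
    ysd <- sqrt(sum(yc^2))
    if (ysd == 0) {
      excluded[[g]] <- tibble(gene = g, peak = peaks$peak[cand],
                              reason = "zero variance")
      next
    }
    ok <- acc_sd[cand] > 0
    if (any(!ok)) {
      excluded[[paste0(g, "_zv")]] <- tibble(gene = g,
                                             peak = peaks$peak[cand[!ok]],
                                             reason = "zero variance")
      cand <- cand[ok]
      if (!length(cand)) next
    }
    robs <- unname(as.numeric(crossprod(acc_ctr[, cand, drop = FALSE], yc)) /
                     (acc_sd[cand] * ysd))
    pvals <- vapply(seq_along(cand), function(ci) {
      # matched background excludes the candidate peak itself; an empty bin
      # falls back to all other peaks
      members <- setdiff(bin_members[[joint[cand[ci]]]], cand[ci])
      if (!length(members)) members <- setdiff(seq_len(nrow(peaks)), cand[ci])
      bg <- if (length(members) >= n_background) {
        sample(members, n_background)
      } else {
        sample(members, n_background, replace = TRUE)
      }
      rbg <- as.numeric(crossprod(acc_ctr[, bg, drop = FALSE], yc)) /
        (pmax(acc_sd[bg], .Machine$double.eps) * ysd)
      (1 + sum(rbg >= robs[ci])) / (1 + n_background)
    }, numeric(1))
    dist_bp <- pmax(genes_use$start[gi] - peaks$end[cand],
                    peaks$start[cand] - genes_use$end[gi], 0)
    links[[g]] <- tibble(gene = g, peak = peaks$peak[cand],
                         r = robs, p = pvals,
                         significant = pvals < p_threshold,
                         distance = dist_bp)
  }
  out <- dplyr::bind_rows(links)
  attr(out, "excluded") <- dplyr::bind_rows(excluded)
  out
}

quantile_bin <- function(x, n_bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Metacell gene scores from linked-peak accessibility
#'
#' The gene score of gene g in metacell m is the sum of normalized
#' accessibility over the peaks significantly linked to g.
#'
#' @param links Link tibble from [correlate_peaks_genes()].
#' @param mc_acc Normalized metacells x peaks matrix.
#' @return A list with `scores` (metacells x genes) and `no_link_genes`
#'   (genes present in links but with no significant peak; scored 0).
#' @export
compute_gene_scores <- function(links, mc_acc) {
  genes <- unique(links$gene)
  sig <- links[links$significant, , drop = FALSE]
  scores <- matrix(0, nrow(mc_acc), length(genes),
                   dimnames = list(rownames(mc_acc), genes))
  by_gene <- split(sig$peak, sig$gene)
  for (g in names(by_gene)) {
    scores[, g] <- rowSums(mc_acc[, by_gene[[g]], drop = FALSE])
  }
  list(scores = scores, no_link_genes = setdiff(genes, names(by_gene)))
}

#' Gene accessibility: fraction of linked peaks open
#'
#' For each gene with at least one significant peak-gene link, the fraction
#' of its linked peaks called open in each metacell — 0 (all closed) to 1
#' (all open).
#'
#' @param open An `open_peaks` result from [call_open_peaks()].
#' @param links Link tibble from [correlate_peaks_genes()].
#' @return Metacells x genes matrix of fractions in \[0, 1\]; genes with no
#'   significant links are excluded.
#' @export
compute_gene_accessibility <- function(open, links) {
  sig <- links[links$significant, , drop = FALSE]
  by_gene <- split(sig$peak, sig$gene)
  openm <- open$open
  out <- matrix(NA_real_, nrow(openm), length(by_gene),
                dimnames = list(rownames(openm), names(by_gene)))
  for (g in names(by_gene)) {
    pk <- by_gene[[g]]
    out[, g] <- Matrix::rowSums(openm[, pk, drop = FALSE]) / length(pk)
  }
  out
}
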