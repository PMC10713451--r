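#' Simulate a multiome single-cell dataset with known ground truth
#'
#' Generates paired RNA and ATAC count matrices from a shared latent cell
#' state, with optional rare populations, planted peak-gene couplings, a toy
#' genome layout, and (on request) an ATAC fragment table with a
#' nucleosome-free/mono-nucleosome length mixture.
#'
#' Each state owns a disjoint block of marker genes and marker peaks whose
#' mean abundance is raised by `marker_fold`; counts are negative binomial
#' (dispersion `dispersion`) around state means scaled by log-normal per-cell
#' library sizes. Planted links tie a peak's cross-state accessibility
#' profile to a gene's cross-state expression profile with blending weight
#' `coupling`. In `mode = "trajectory"` the state programs become anchors
#' along a latent 1-D pseudotime and each cell's program is the linear
#' interpolation at its pseudotime.
#'
#' @param n_cells,n_genes,n_peaks,n_states Dataset dimensions (defaults
#'   10000, 1500, 3000, 20).
#' @param rare_fractions Numeric vector of planted rare-state frequencies
#'   (for example `0.002`); the last states take these frequencies and the
#'   rest share the remainder equally. Empty for none.
#' @param n_links Number of planted peak-gene couplings (default 50).
#' @param coupling Blend in \[0, 1\] between the linked gene's state profile
#'   and a flat profile for the planted peak (default 0.8).
#' @param marker_fold Fold elevation of marker features (default 8).
#' @param dispersion Negative binomial dispersion (default 0.5; NB size
#'   = 1/dispersion).
#' @param mean_rna_counts,mean_atac_counts Median library sizes (defaults
#'   2500 and 3000).
#' @param nfr_weight Weight of the nucleosome-free (< 147 bp) component of
#'   the fragment-length mixture (default 0.6).
#' @param fragments If `TRUE`, also emit a fragment tibble (one record per
#'   ATAC count); keep `n_cells` modest when requesting this.
#' @param modalities Which count matrices to generate (`"rna"`, `"atac"`, or
#'   both, the default); skipping a modality saves time and memory at large
#'   `n_cells`.
#' @param mode `"discrete"` states or a `"trajectory"` continuum.
#' @param seed Seed; identical seeds give byte-identical output.
#'
#' @return A list with `rna` and `atac` [cell_matrix()] objects, `peaks`
#'   (tibble: peak, chrom, start, end, gc), `genes` (tibble: gene, chrom,
#'   start, end), optional `fragments`, and `truth` (state labels,
#'   frequencies, programs, planted links, mixture parameters, seed).
#' @export
simulate_multiome <- function(n_cells = 10000, n_genes = 1500, n_peaks = 3000,
                              n_states = 20, rare_fractions = numeric(0),
                              n_links = 50, coupling = 0.8, marker_fold = 8,
                              dispersion = 0.5,
                              mean_rna_counts = 2500, mean_atac_counts = 3000,
                              nfr_weight = 0.6, fragments = FALSE,
                              modalities = c("rna", "atac"),
                              mode = c("discrete", "trajectory"), seed = 0) {
  mode <- match.arg(mode)
  modalities <- match.arg(modalities, several.ok = TRUE)
  stopifnot(n_cells > 1, n_genes > 1, n_peaks > 1, n_states > 1)
  if (length(rare_fractions)) {
    if (any(rare_fractions * n_cells < 1)) {
      abort("a rare fraction times n_cells is below one cell")
    }
    if (length(rare_fractions) >= n_states) abort("more rare states than states")
  }
  set.seed(derive_seed(seed, 101))

  freqs <- state_frequencies(n_states, rare_fractions)
  target <- pmax(round(freqs * n_cells), 1)
  target[which.max(target)] <- target[which.max(target)] + (n_cells - sum(target))
  labels <- sample(rep(seq_len(n_states), target))

  # disjoint marker blocks; baseline relative abundances from a gamma
  gene_prog <- make_programs(n_states, n_genes, marker_fold)
  peak_prog <- make_programs(n_states, n_peaks, marker_fold)

  # toy genome: genes every 50 kb on a few contigs, peaks scattered around genes
  layout <- toy_genome(n_genes, n_peaks, seed)
  links <- plant_links(layout, n_links, derive_seed(seed, 104))
  for (r in seq_len(nrow(links$table))) {
    g <- links$table$gene_index[r]; k <- links$table$peak_index[r]
    prof <- gene_prog[, g] / sum(gene_prog[, g])
    peak_prog[, k] <- coupling * prof + (1 - coupling) / n_states
  }
  gene_prog <- sweep(gene_prog, 1, rowSums(gene_prog), "/")
  peak_prog <- sweep(peak_prog, 1, rowSums(peak_prog), "/")

  tau <- NULL
  if (mode == "trajectory") {
    tau <- sort(runif(n_cells))
    gene_mix <- trajectory_mix(tau, n_states)
    gene_fn <- function(rows) gene_mix[rows, , drop = FALSE] %*% gene_prog
    peak_fn <- function(rows) gene_mix[rows, , drop = FALSE] %*% peak_prog
  } else {
    gene_fn <- function(rows) gene_prog[labels[rows], , drop = FALSE]
    peak_fn <- function(rows) peak_prog[labels[rows], , drop = FALSE]
  }

  lib_rna <- exp(rnorm(n_cells, log(mean_rna_counts), 0.3))
  lib_atac <- exp(rnorm(n_cells, log(mean_atac_counts), 0.3))
  size <- 1 / dispersion
  cells <- sprintf("cell_%05d", seq_len(n_cells))
  genes <- layout$genes$gene
  peaks <- layout$peaks$peak

  rna <- atac <- NULL
  if ("rna" %in% modalities) {
    rna <- nb_counts(gene_fn, n_cells, lib_rna, size)
    rna <- cell_matrix(`dimnames<-`(rna, list(cells, genes)), modality = "rna")
  }
  if ("atac" %in% modalities) {
    atac <- nb_counts(peak_fn, n_cells, lib_atac, size)
    atac <- cell_matrix(`dimnames<-`(atac, list(cells, peaks)), modality = "atac")
  }

  frg <- NULL
  if (fragments) {
    if (is.null(atac)) abort("fragments = TRUE requires the atac modality")
    frg <- fragments_from_counts(atac, layout$peaks, nfr_weight,
                                 derive_seed(seed, 102))
  }
  list(rna = rna, atac = atac,
       peaks = layout$peaks, genes = layout$genes, fragments = frg,
       truth = list(state = labels, frequencies = freqs,
                    pseudotime = tau,
                    gene_programs = gene_prog, peak_programs = peak_prog,
                    links = links$table, coupling = coupling,
                    nfr_weight = nfr_weight,
                    length_modes = c(nfr = 80, nucleosome = 200),
                    dispersion = dispersion, seed = seed))
}

state_frequencies <- function(n_states, rare_fractions) {
  n_rare <- length(rare_fractions)
  rest <- (1 - sum(rare_fractions)) / (n_states - n_rare)
  c(rep(rest, n_states - n_rare), rare_fractions)
}

make_programs <- function(n_states, n_features, marker_fold) {
  base <- matrix(rep(stats::rgamma(n_features, 2, 2) + 0.05, each = n_states),
                 n_states, n_features)
  block <- floor(n_features / n_states)
  for (s in seq_len(n_states)) {
    idx <- ((s - 1) * block + 1):(s * block)
    base[s, idx] <- base[s, idx] * marker_fold
  }
  base
}

trajectory_mix <- function(tau, n_states) {
  anchors <- seq(0, 1, length.out = n_states)
  mix <- matrix(0, length(tau), n_states)
  seg <- pmin(findInterval(tau, anchors, rightmost.closed = TRUE), n_states - 1)
  w <- (tau - anchors[seg]) / (anchors[seg + 1] - anchors[seg])
  mix[cbind(seq_along(tau), seg)] <- 1 - w
  mix[cbind(seq_along(tau), seg + 1)] <- w
  mix
}

# negative binomial draws in row blocks to bound transient dense memory;
# prob_fn(rows) returns the cells x features probability block
nb_counts <- function(prob_fn, n, lib, size, block = 4000L) {
  out <- vector("list", ceiling(n / block))
  for (bi in seq_along(out)) {
    rows <- (((bi - 1L) * block + 1L)):min(bi * block, n)
    mu <- prob_fn(rows) * lib[rows]
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                     nrow = length(rows))
    out[[bi]] <- as(as(counts, "dMatrix"), "CsparseMatrix")
  }
  do.call(rbind, out)
}

toy_genome <- function(n_genes, n_peaks, seed) {
  set.seed(derive_seed(seed, 103))
  per_chrom <- 500
  gi <- seq_len(n_genes) - 1
  genes <- tibble(
    gene = sprintf("gene_%04d", seq_len(n_genes)),
    chrom = paste0("chr", gi %/% per_chrom + 1),
    start = (gi %% per_chrom) * 50000 + 10000,
    end = (gi %% per_chrom) * 50000 + 12000)
  anchor <- rep(seq_len(n_genes), length.out = n_peaks)
  offset <- sample(c(-1, 1), n_peaks, replace = TRUE) *
    sample(2000:80000, n_peaks, replace = TRUE)
  centers <- pmax(genes$start[anchor] + offset, 500)
  peaks <- tibble(
    peak = sprintf("peak_%05d", seq_len(n_peaks)),
    chrom = genes$chrom[anchor],
    start = centers - 250,
    end = centers + 250,
    gc = round(runif(n_peaks, 0.3, 0.7), 4),
    anchor_gene = anchor)
  list(genes = genes, peaks = peaks)
}

plant_links <- function(layout, n_links, seed) {
  set.seed(seed)
  cand_peaks <- sample(nrow(layout$peaks), min(n_links, nrow(layout$peaks)))
  tbl <- tibble(
    gene_index = layout$peaks$anchor_gene[cand_peaks],
    peak_index = cand_peaks,
    gene = layout$genes$gene[layout$peaks$anchor_gene[cand_peaks]],
    peak = layout$peaks$peak[cand_peaks])
  tbl <- dplyr::distinct(tbl, .data$gene_index, .keep_all = TRUE)
  list(table = tbl)
}

# one fragment record per ATAC count unit, length from the two-mode mixture
fragments_from_counts <- function(atac, peaks, nfr_weight, seed) {
  set.seed(seed)
  m <- as_dgc(atac)
  tm <- as(m, "TsparseMatrix")
  reps <- as.integer(tm@x)
  cell_idx <- rep(tm@i + 1L, reps)
  peak_idx <- rep(tm@j + 1L, reps)
  nfrag <- length(cell_idx)
  is_nfr <- runif(nfrag) < nfr_weight
  len <- integer(nfrag)
  len[is_nfr] <- pmin(pmax(round(rnorm(sum(is_nfr), 80, 20)), 20), 146)
  len[!is_nfr] <- pmin(pmax(round(rnorm(sum(!is_nfr), 200, 30)), 147), 350)
  width <- peaks$end[peak_idx] - peaks$start[peak_idx]
  start <- peaks$start[peak_idx] +
    floor(runif(nfrag) * pmax(width, 1))
  out <- tibble(chrom = peaks$chrom[peak_idx],
                start = start,
                end = start + len,
                barcode = rownames(m)[cell_idx],
                count = 1L)
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Simulate a multi-sample cohort with condition-enriched states
#'
#' Samples share one latent state space; designated states are
#' over-represented in the second condition by `effect_size` (frequency
#' multiplier before renormalization). Per-sample library-size shifts mimic
#' batch structure. `effect_size = 1` gives a fully exchangeable null.
#'
#' @param n_samples Named integer vector of samples per condition, for
#'   example `c(healthy = 4, disease = 4)`.
#' @param n_cells_per_sample Cells per sample (default 1000).
#' @param n_genes,n_states Shared dimensions (defaults 1000, 8).
#' @param enriched_states State indices enriched in the second condition
#'   (default 1).
#' @param effect_size Frequency multiplier for enriched states (default 3).
#' @param marker_fold,dispersion As in [simulate_multiome()].
#' @param seed Seed.
#'
#' @return A list with `samples` (named list of RNA `cell_matrix`),
#'   `manifest` (tibble: sample_id, condition, n_cells), `celltypes` (named
#'   list of per-cell state labels), and `truth`.
#' @export
simulate_cohort <- function(n_samples = c(healthy = 4, disease = 4),
                            n_cells_per_sample = 1000,
                            n_genes = 1000, n_states = 8,
                            enriched_states = 1, effect_size = 3,
                            marker_fold = 3, dispersion = 0.5, seed = 0) {
  stopifnot(length(n_samples) >= 1, all(n_samples >= 1))
  conds <- names(n_samples) %||% paste0("cond", seq_along(n_samples))
  set.seed(derive_seed(seed, 201))
  prog <- make_programs(n_states, n_genes, marker_fold)
  prog <- sweep(prog, 1, rowSums(prog), "/")
  base_freq <- rep(1 / n_states, n_states)
  samples <- list(); celltypes <- list(); manifest <- list()
  idx <- 0
  for (ci in seq_along(n_samples)) {
    freq <- base_freq
    if (ci == 2) {
      freq[enriched_states] <- freq[enriched_states] * effect_size
      freq <- freq / sum(freq)
    }
    for (r in seq_len(n_samples[ci])) {
      idx <- idx + 1
      sid <- sprintf("%s_%d", conds[ci], r)
      set.seed(derive_seed(seed, 210 + idx))
      lab <- sample(seq_len(n_states), n_cells_per_sample, replace = TRUE,
                    prob = freq)
      lib <- exp(rnorm(n_cells_per_sample, log(2000), 0.3)) *
        exp(rnorm(1, 0, 0.2))   # sample-level depth shift
      counts <- nb_counts(function(rows) prog[lab[rows], , drop = FALSE],
                          n_cells_per_sample, lib, 1 / dispersion)
      dimnames(counts) <- list(sprintf("%s_cell_%04d", sid,
                                       seq_len(n_cells_per_sample)),
                               sprintf("gene_%04d", seq_len(n_genes)))
      samples[[sid]] <- cell_matrix(counts, modality = "rna")
      celltypes[[sid]] <- paste0("state_", lab)
      manifest[[idx]] <- tibble(sample_id = sid, condition = conds[ci],
                                n_cells = n_cells_per_sample)
    }
  }
  list(samples = samples,
       manifest = dplyr::bind_rows(manifest),
       celltypes = celltypes,
       truth = list(programs = prog, enriched_states = enriched_states,
                    effect_size = effect_size, n_states = n_states,
                    conditions = conds, seed = seed))
}
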