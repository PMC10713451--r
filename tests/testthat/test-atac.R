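make_fragments <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 100L, 500L, 40L),
    end = c(246L, 247L, 580L, 180L),
    barcode = c("bc1", "bc1", "bc2", "bc3"),
    count = c(1L, 1L, 2L, 1L))
}

test_that("NFR filter keeps fragments strictly below the length bound", {
  frg <- make_fragments()
  kept <- filter_nfr_fragments(frg)
  lens <- kept$end - kept$start
  expect_true(all(lens < 147))
  expect_equal(nrow(kept), 3)                       # length 146 kept, 147 removed
  expect_equal(attr(kept, "retained_fraction"), 3 / 4)
  # retained + removed partition the input
  removed <- frg[(frg$end - frg$start) >= 147, ]
  expect_equal(nrow(kept) + nrow(removed), nrow(frg))
  empty <- frg[0, ]
  expect_equal(nrow(filter_nfr_fragments(empty)), 0)
  bad <- frg; bad$end[2] <- bad$start[2]
  expect_error(filter_nfr_fragments(bad), "row")
})

test_that("fragments are counted per peak by Tn5 insertion sites, once each", {
  peaks <- tibble::tibble(peak = c("p1", "p2"), chrom = "chr1",
                          start = c(90L, 560L), end = c(140L, 620L))
  frg <- tibble::tibble(chrom = "chr1",
                        start = c(100L, 30L, 565L, 100L),
                        end = c(400L, 120L, 600L, 130L),
                        barcode = c("bc1", "bc1", "bc2", "bc2"),
                        count = 1L)
  asg <- structure(list(labels = c(1L, 2L), s = 2), class = "metacell_assignment")
  res <- count_peak_fragments(frg, peaks, c("bc1", "bc2"), asg)
  # bc1: frag1 start in p1 (end outside) counts once; frag2 end-1=119 in p1
  expect_equal(as.numeric(res$counts[1, ]), c(2, 0))
  # bc2: frag3 both insertions in p2 -> once; frag4 both insertions in p1
  expect_equal(as.numeric(res$counts[2, ]), c(1, 1))
  expect_equal(res$totals, c(2, 2))
  # no fragments -> all-zero matrix
  res0 <- count_peak_fragments(frg[0, ], peaks, c("bc1", "bc2"), asg)
  expect_equal(sum(res0$counts), 0)
})

test_that("augmented counting pools each metacell with its two nearest", {
  peaks <- tibble::tibble(peak = "p1", chrom = "chr1", start = 0L, end = 1000L)
  frg <- tibble::tibble(chrom = "chr1", start = c(10L, 20L, 30L, 40L),
                        end = c(110L, 120L, 130L, 140L),
                        barcode = paste0("bc", 1:4), count = 1L)
  asg <- structure(list(labels = 1:4, s = 4), class = "metacell_assignment")
  dcs <- matrix(c(0, 1, 10, 11), 4, 1)
  plain <- count_peak_fragments(frg, peaks, paste0("bc", 1:4), asg)
  aug <- count_peak_fragments(frg, peaks, paste0("bc", 1:4), asg,
                              augment = TRUE, dcs = dcs)
  # each row pools itself and its two nearest centroids
  expect_equal(as.numeric(aug$counts[, 1]), rep(3, 4))
  expect_equal(aug$totals, rep(3, 4))
  expect_equal(sum(plain$counts), 4)
})

test_that("Poisson open-peak rate and tail follow the printed formula", {
  counts <- matrix(0, 1, 1000)
  counts[1, 1:5] <- c(30, 25, 2, 0, 10)
  op <- call_open_peaks(counts, totals = 100000)
  expect_equal(op$lambda, 10)                       # 500*1e5/(1000*5000)
  expect_equal(op$p_values[1, 4], 1 - exp(-10))     # P(X > 0)
  expect_true(op$p_values[1, 4] > 0.99)
  expect_equal(unname(as.matrix(op$open)[1, 1:5] > 0),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_warning(call_open_peaks(matrix(0, 1, 10), totals = 0), "zero total")
})

test_that("Poisson survival p equals brute-force pmf summation", {
  for (lambda in c(0.1, 1, 10, 50)) {
    n <- 0:200
    p_sf <- ppois(n, lambda, lower.tail = FALSE)
    p_brute <- vapply(n, function(k) {
      1 - sum(dpois(0:k, lambda))
    }, numeric(1))
    expect_lt(max(abs(p_sf - p_brute)), 1e-12)
  }
})

peak_gene_fixture <- function(n_mc = 30, n_peaks = 40, seed = 11) {
  set.seed(seed)
  peaks <- tibble::tibble(
    peak = sprintf("pk%02d", 1:n_peaks), chrom = "chr1",
    start = seq(0, by = 5000, length.out = n_peaks),
    end = seq(500, by = 5000, length.out = n_peaks),
    gc = runif(n_peaks, 0.3, 0.7))
  genes <- tibble::tibble(gene = c("gA", "gB"), chrom = "chr1",
                          start = c(1000L, 50000L), end = c(3000L, 52000L))
  expr <- cbind(gA = rnorm(n_mc), gB = rnorm(n_mc))
  acc <- matrix(rnorm(n_mc * n_peaks), n_mc, n_peaks,
                dimnames = list(NULL, peaks$peak))
  acc[, 1] <- expr[, "gA"]            # peak 1 tracks gene A exactly
  list(peaks = peaks, genes = genes, expr = expr, acc = acc)
}

test_that("peak-gene links recover exact coupling with the add-one empirical p", {
  fx <- peak_gene_fixture()
  links <- correlate_peaks_genes(fx$expr, fx$acc, fx$genes, fx$peaks,
                                 n_bins = 4, seed = 1)
  l1 <- links[links$gene == "gA" & links$peak == "pk01", ]
  expect_equal(l1$r, 1)
  expect_equal(l1$p, 1 / 101)         # observed r above all 100 draws
  expect_true(l1$significant)
  expect_true(all(links$p > 0 & links$p <= 1))
  expect_true(all(abs(links$r) <= 1 + 1e-12))
  # candidate windows: gB at 50kb only sees peaks within 100kb
  expect_true(all(links$distance <= 100000))
})

test_that("zero-variance vectors are excluded with a reason", {
  fx <- peak_gene_fixture()
  fx$acc[, 2] <- 5                    # constant accessibility
  links <- correlate_peaks_genes(fx$expr, fx$acc, fx$genes, fx$peaks,
                                 n_bins = 4, seed = 1)
  exc <- attr(links, "excluded")
  expect_true("pk02" %in% exc$peak)
  expect_true(all(exc$reason == "zero variance"))
  expect_false("pk02" %in% links$peak)
})

test_that("gene scores sum linked-peak accessibility and never decrease with links", {
  links <- tibble::tibble(gene = c("g1", "g1", "g2"),
                          peak = c("p1", "p2", "p3"),
                          r = c(0.9, 0.8, 0.2), p = c(0.01, 0.05, 0.5),
                          significant = c(TRUE, TRUE, FALSE))
  acc <- matrix(c(0.3, 0.7, 0.4), 1, 3, dimnames = list("mc_1", c("p1", "p2", "p3")))
  gs <- compute_gene_scores(links, acc)
  expect_equal(gs$scores[1, "g1"], 1.0)
  expect_equal(gs$scores[1, "g2"], 0)
  expect_true("g2" %in% gs$no_link_genes)
})

test_that("gene accessibility is the open fraction of linked peaks", {
  links <- tibble::tibble(gene = rep("g1", 4), peak = paste0("p", 1:4),
                          r = 0.5, p = 0.01, significant = TRUE)
  open <- structure(list(open = as(matrix(c(1, 0, 1, 0), 1, 4,
                                          dimnames = list("mc_1", paste0("p", 1:4))),
                                   "CsparseMatrix")), class = "open_peaks")
  ga <- compute_gene_accessibility(open, links)
  expect_equal(ga[1, "g1"], 0.5)
  open$open[1, ] <- 1
  expect_equal(compute_gene_accessibility(open, links)[1, "g1"], 1)
  open$open[1, ] <- 0
  expect_equal(compute_gene_accessibility(open, links)[1, "g1"], 0)
})
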