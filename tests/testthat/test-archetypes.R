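test_that("max-min waypoints spread over extremes and respect counts", {
  # 1-D values {0, 1, 10}: from 0 the farthest point is 10
  picks <- metacellkit:::maxmin_1d(c(0, 1, 10), 2, start = 1)
  expect_equal(picks, c(1L, 3L))
  kern <- random_kernel(n = 30, seed = 2)
  dm <- suppressWarnings(diffusion_map(kern, n_dcs = 3))
  wp <- sample_waypoints(dm, kern, 30, seed = 1)
  expect_setequal(wp, 1:30)   # n_waypoints = n returns every cell
  wp2 <- sample_waypoints(dm, kern, 10, seed = 1)
  expect_length(unique(wp2), 10)
  expect_error(sample_waypoints(dm, kern, 31), "exceed")
})

test_that("waypoint sets are seed-deterministic and shortfall is greedily filled", {
  kern <- random_kernel(n = 40, seed = 3)
  dm <- suppressWarnings(diffusion_map(kern, n_dcs = 3))
  expect_identical(sample_waypoints(dm, kern, 12, seed = 5),
                   sample_waypoints(dm, kern, 12, seed = 5))
  # maxmin_proportion = 0 forces a pure greedy column-subset selection
  wp_css <- sample_waypoints(dm, kern, 8, maxmin_proportion = 0, seed = 1)
  expect_length(unique(wp_css), 8)
})

test_that("reconstruction error via trace identity equals the dense Frobenius norm", {
  set.seed(9)
  kern <- random_kernel(n = 25, seed = 4)
  m <- kern$affinities
  s <- 4
  a <- matrix(runif(s * 25), s, 25); a <- sweep(a, 2, colSums(a), "/")
  b <- matrix(runif(25 * s), 25, s); b <- sweep(b, 2, colSums(b), "/")
  expect_equal(reconstruction_error(kern, a, b), dense_sre(m, a, b),
               tolerance = 1e-10)
  # exact decomposition gives zero error
  expect_lt(reconstruction_error(m, Diagonal(25), Diagonal(25)), 1e-20)
  expect_error(reconstruction_error(kern, a[, -1], b), "shape mismatch")
})

test_that("fitted decompositions are column-stochastic with monotone SRE", {
  for (seed in 1:5) {
    kern <- random_kernel(n = 35, seed = seed)
    set.seed(seed)
    dec <- fit_kernel_archetypes(kern, s = 5, init = sample(35, 5))
    expect_lt(max(abs(Matrix::colSums(dec$A) - 1)), 1e-9)
    expect_lt(max(abs(Matrix::colSums(dec$B) - 1)), 1e-9)
    expect_gte(min(dec$A@x), 0)
    expect_gte(min(dec$B@x), 0)
    expect_true(all(diff(dec$sre_trace) <= 1e-9))
  }
})

test_that("block kernels recover the planted partition at the exhaustive optimum", {
  kern <- block_kernel(n_per_block = 3)
  dec <- fit_kernel_archetypes(kern, s = 2, init = c(1, 4))
  asg <- hard_assignments(dec)
  expect_equal(length(unique(asg$labels[1:3])), 1)
  expect_equal(length(unique(asg$labels[4:6])), 1)
  expect_false(asg$labels[1] == asg$labels[4])
  best <- exhaustive_best_sre(kern, 2)
  expect_lt(tail(dec$sre_trace, 1), best + 1e-6)
})

test_that("identity initialization with s = n reconstructs the kernel exactly", {
  kern <- random_kernel(n = 12, seed = 6)
  dec <- fit_kernel_archetypes(kern, s = 12, init = 1:12)
  expect_lt(tail(dec$sre_trace, 1), 1e-10 * sum(kern$affinities@x^2))
  expect_error(fit_kernel_archetypes(kern, s = 13, init = 1:13), "more archetypes")
})

test_that("fits are bit-reproducible under a fixed seed", {
  kern <- random_kernel(n = 30, seed = 7)
  dm <- suppressWarnings(diffusion_map(kern, n_dcs = 3))
  wp1 <- sample_waypoints(dm, kern, 6, seed = 3)
  wp2 <- sample_waypoints(dm, kern, 6, seed = 3)
  d1 <- fit_kernel_archetypes(kern, 6, wp1)
  d2 <- fit_kernel_archetypes(kern, 6, wp2)
  expect_identical(d1$A, d2$A)
  expect_identical(d1$B, d2$B)
  expect_identical(d1$sre_trace, d2$sre_trace)
})

test_that("hard assignment zeroes trivial weights, renormalizes and tie-breaks low", {
  a <- cbind(c(0.96, 0.04), c(0.5, 0.5), c(0.03, 0.97))
  dec <- structure(list(A = as(a, "CsparseMatrix"), s = 2), class = "decomposition")
  asg <- hard_assignments(dec, trivial_threshold = 0.05)
  expect_equal(asg$soft_weights[, 1], c(1, 0))
  expect_equal(asg$labels[1], 1L)
  expect_equal(asg$labels[2], 1L)          # exact tie goes to the lowest index
  expect_equal(asg$labels[3], 2L)
  expect_equal(Matrix::colSums(asg$soft_weights), rep(1, 3))
  expect_equal(asg$n_nontrivial, c(1, 2, 1))
  # all-below-threshold column falls back to pre-threshold argmax with warning
  a2 <- cbind(c(0.5, 0.5), c(0.04, 0.96)) # make 3 archetypes w tiny weights
  a3 <- rbind(a2, 0)
  a3[, 1] <- c(0.035, 0.04, 0.925)
  dec3 <- structure(list(A = as(a3, "CsparseMatrix"), s = 3), class = "decomposition")
  expect_silent(hard_assignments(dec3))
  a4 <- matrix(rep(1 / 30, 30), 30, 1)
  dec4 <- structure(list(A = as(a4, "CsparseMatrix"), s = 30), class = "decomposition")
  expect_warning(hard_assignments(dec4), "below")
})

test_that("aggregation conserves counts and drops empty metacells", {
  cm <- tiny_counts(rbind(c(1, 0), c(2, 3), c(4, 1)))
  asg <- structure(list(labels = c(1L, 1L, 3L), s = 3), class = "metacell_assignment")
  expect_warning(aggregate_metacell_counts(cm, asg), "empty")
  mc <- suppressWarnings(aggregate_metacell_counts(cm, asg))
  expect_equal(nrow(mc$values), 2)
  expect_equal(as.numeric(mc$values[1, ]), c(3, 3))
  expect_equal(sum(mc$values), sum(cm))
  expect_equal(mc$sizes, c(2L, 1L))
  # permutation invariance
  perm <- c(3, 1, 2)
  cmp <- tiny_counts(as.matrix(cm)[perm, ])
  asgp <- structure(list(labels = c(3L, 1L, 1L), s = 3), class = "metacell_assignment")
  mcp <- suppressWarnings(aggregate_metacell_counts(cmp, asgp))
  expect_equal(as.matrix(mcp$values), as.matrix(mc$values))
  asg_bad <- structure(list(labels = c(1L, 5L, 1L), s = 3), class = "metacell_assignment")
  expect_error(aggregate_metacell_counts(cm, asg_bad), "out of range")
})

test_that("metacell normalization applies the median-rescale log transform", {
  vals <- rbind(c(0, 10), c(5, 5), c(20, 0))
  mc <- structure(list(values = as(vals, "CsparseMatrix")), class = "metacell_counts")
  norm <- normalize_metacell_counts(mc)
  med <- median(rowSums(vals))
  expect_equal(norm[1, 1], log(0.1))
  expect_equal(norm[1, 2], log(10 / 10 * med + 0.1))
  expect_equal(norm[2, 1], log(5 / 10 * med + 0.1))
  # equal totals mean a unit scaling factor
  eq <- structure(list(values = as(rbind(c(1, 3), c(2, 2)), "CsparseMatrix")),
                  class = "metacell_counts")
  expect_equal(normalize_metacell_counts(eq)[1, 1], log(1 + 0.1))
  zero <- structure(list(values = as(rbind(c(1, 1), c(0, 0)), "CsparseMatrix")),
                    class = "metacell_counts")
  expect_error(normalize_metacell_counts(zero), "zero total")
})

test_that("metacell count heuristic rounds up and honors overrides", {
  expect_equal(suggest_n_metacells(6800), 91L)
  expect_equal(suggest_n_metacells(75), 1L)
  expect_equal(suggest_n_metacells(2300, 230), 10L)
  expect_error(suggest_n_metacells(10, 75), "at least")
})

test_that("assignment confidence bins partition all cells with quoted edges", {
  asg <- structure(list(max_weight = c(0.3, 0.5, 0.79, 0.8, 0.89, 0.9, 1),
                        n_nontrivial = c(3, 2, 2, 1, 1, 1, 1)),
                   class = "metacell_assignment")
  s <- summarize_assignment_confidence(asg)
  expect_equal(s$weight_bins$n, c(1L, 2L, 2L, 2L))
  expect_equal(sum(s$weight_bins$n), 7)
  expect_equal(s$weight_bins$bin,
               c("[0,0.5)", "[0.5,0.8)", "[0.8,0.9)", "[0.9,1]"))
})
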