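# two-sample embedding with two clearly separated states per sample
paired_embedding <- function(n_per_state = 6, jitter = 0.05, seed = 51) {
  set.seed(seed)
  one <- function() rbind(
    matrix(rnorm(n_per_state * 2, 0, jitter), n_per_state, 2),
    matrix(rnorm(n_per_state * 2, 50, jitter), n_per_state, 2))
  emb <- rbind(one(), one())
  list(embedding = emb,
       sample_ids = rep(c("s1", "s2"), each = 2 * n_per_state),
       types = rep(rep(c("alpha", "beta"), each = n_per_state), 2))
}

test_that("identical samples map one-to-one with matching types", {
  fx <- paired_embedding()
  res <- map_metacells_between_samples(fx$embedding, fx$sample_ids,
                                       n_dcs = 3, types = fx$types)
  expect_gt(nrow(res$pairs), 0)
  expect_equal(res$matched_fraction, 1)
  # each unordered pair appears once
  key <- paste(pmin(res$pairs$metacell_a, res$pairs$metacell_b),
               pmax(res$pairs$metacell_a, res$pairs$metacell_b))
  expect_false(any(duplicated(key)))
  # no cross-state pairs: inter-state distance dwarfs intra-state
  ta <- fx$types[res$pairs$metacell_a]
  tb <- fx$types[res$pairs$metacell_b]
  expect_true(all(ta == tb))
})

test_that("small samples are excluded from mapping with a warning", {
  fx <- paired_embedding()
  ids <- fx$sample_ids
  ids[23:24] <- "s3"   # s3 keeps only 2 metacells
  expect_warning(
    res <- map_metacells_between_samples(fx$embedding, ids, n_dcs = 3),
    "excluded")
  expect_true(all(res$pairs$sample_a != "s3" & res$pairs$sample_b != "s3"))
})

meta2_fixture <- function(n_mc = 80, enrich = NULL, seed = 52) {
  set.seed(seed)
  emb <- rbind(matrix(rnorm(n_mc, 0, 0.3), n_mc / 2, 2),
               matrix(rnorm(n_mc, 30, 0.3), n_mc / 2, 2))
  cond <- sample(rep(c("healthy", "disease"), n_mc / 2))
  if (!is.null(enrich)) {
    # the first state becomes disease-heavy
    cond[seq_len(n_mc / 2)] <- sample(c("healthy", "disease"), n_mc / 2,
                                      replace = TRUE, prob = c(1 - enrich, enrich))
  }
  info <- tibble::tibble(condition = cond,
                         celltype = rep(c("tA", "tB"), each = n_mc / 2),
                         size = rep(10L, n_mc))
  list(embedding = emb, info = info)
}

test_that("meta2cells honor the ratio heuristic and the 80% purity rule", {
  fx <- meta2_fixture()
  m2 <- build_meta2cells(fx$embedding, fx$info, ratio = 10, seed = 1,
                         disease_condition = "disease")
  expect_lte(max(m2$labels), ceiling(80 / 10))
  expect_true(all(m2$summary$proportion >= 0 & m2$summary$proportion <= 1))
  # states are well separated: annotations resolve to a pure type
  expect_true(all(m2$summary$annotation %in% c("tA", "tB")))
  # size-weighted proportions average to the cohort disease fraction
  w <- m2$summary$n_metacells
  expect_equal(sum(m2$summary$proportion * w) / sum(w),
               mean(fx$info$condition == "disease"), tolerance = 1e-12)
})

test_that("mixed meta2cells fall back to the Mixed annotation", {
  fx <- meta2_fixture()
  fx$info$celltype <- rep(c("tA", "tB"), 40)   # interleaved types
  m2 <- build_meta2cells(fx$embedding, fx$info, ratio = 10, seed = 1,
                         disease_condition = "disease")
  expect_true(any(m2$summary$annotation == "Mixed"))
})

test_that("permutation p-values are add-one bounded, preserve sizes and flag planting", {
  fx <- meta2_fixture(enrich = 0.95)
  m2 <- build_meta2cells(fx$embedding, fx$info, ratio = 10, seed = 2,
                         disease_condition = "disease")
  da <- test_differential_abundance(m2, n_permutations = 500, seed = 3)
  expect_true(all(da$p > 0 & da$p <= 1))
  expect_gte(min(da$p), 1 / 501)
  expect_equal(sum(da$n_metacells), 80)
  # the disease-heavy state is detected
  enriched <- da[da$proportion > 0.75, ]
  expect_true(any(enriched$significant))
  expect_error(test_differential_abundance(m2, n_permutations = 50), "at least 100")
  # deterministic under the seed
  da2 <- test_differential_abundance(m2, n_permutations = 500, seed = 3)
  expect_identical(da$p, da2$p)
})

test_that("single-condition cohorts yield p = 1 everywhere", {
  fx <- meta2_fixture()
  fx$info$condition <- "disease"
  m2 <- suppressWarnings(build_meta2cells(fx$embedding, fx$info, seed = 1))
  da <- test_differential_abundance(m2, n_permutations = 200, seed = 1)
  expect_true(all(da$p == 1))
  expect_false(any(da$significant))
  expect_true(all(da$proportion == 1))
})

test_that("per-sample cohort runs tag metacells with sample and condition", {
  sim <- simulate_cohort(n_samples = c(healthy = 1, disease = 1),
                         n_cells_per_sample = 300, n_genes = 300,
                         n_states = 3, seed = 4)
  ca <- suppressWarnings(
    cohort_metacells(sim$samples, sim$manifest, celltypes = sim$celltypes,
                     n_components = 20, n_hvg = 300, seed = 1))
  expect_s3_class(ca, "cohort_assignment")
  expect_equal(sort(unique(ca$metacells$condition)), c("disease", "healthy"))
  expect_equal(nrow(ca$expression), nrow(ca$metacells))
  expect_equal(sum(ca$metacells$size), 600)
  expect_equal(median(ca$metacells$purity), 1)
  expect_gt(mean(ca$metacells$purity), 0.8)
})
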