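# Richness, rarefaction, normalization, Bray-Curtis and PCoA.

toy_otutab <- function(counts, reps = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- paste0("Cluster_", seq_len(nrow(counts)))
  if (is.null(reps))
    reps <- setNames(vapply(seq_len(nrow(counts)),
                            function(i) random_dna_str(40), character(1)),
                     rownames(counts))
  structure(list(counts = counts, representatives = reps,
                 members = as.list(reps), d = 3L), class = "otutab")
}

test_that("richness counts nonzero OTUs and merges by assigned rank", {
  set.seed(61)
  ot <- toy_otutab(cbind(S1 = c(5, 3, 2, 0)))
  expect_identical(unname(richness(ot)), 3L)
  a <- data.frame(otu_id = rownames(ot$counts),
                  genus = c("X", "X", "X", "Y"),
                  species = c("X a", "X b", "X a", "Y c"),
                  stringsAsFactors = FALSE)
  expect_identical(unname(richness(ot, "genus", a)), 1L)
  expect_identical(unname(richness(ot, "species", a)), 2L)
  # genus richness never exceeds OTU richness
  for (k in 1:5) {
    cnt <- cbind(S = rpois(6, 3))
    ot2 <- toy_otutab(cnt)
    a2 <- data.frame(otu_id = rownames(ot2$counts),
                     genus = sample(c("g1", "g2", "g3"), 6, TRUE),
                     stringsAsFactors = FALSE)
    expect_lte(unname(richness(ot2, "genus", a2)), unname(richness(ot2)))
  }
})

test_that("rarefaction expectation matches the hypergeometric closed form", {
  # counts (5,5), n = 2: 2 * (1 - C(5,2)/C(10,2)) = 14/9
  expect_equal(rarefy_expected(c(5, 5), 2), 14 / 9, tolerance = 1e-12)
  expect_equal(rarefy_expected(c(5, 5), 0), 0)
  expect_equal(rarefy_expected(c(5, 5), 10), 2)
  expect_equal(rarefy_expected(c(3, 1, 7), 11), 3)   # n = N: observed richness
  expect_error(rarefy_expected(c(5, 5), 11), "total")
})

test_that("rarefaction expectation agrees with Monte-Carlo subsampling", {
  set.seed(62)
  for (k in 1:3) {
    # singletons plus a range of abundances keep the subsample outcome
    # genuinely random (a degenerate draw has zero Monte-Carlo SE)
    counts <- c(rpois(8, lambda = sample(3:20, 1)) + 1L, 1L, 1L)
    N <- sum(counts)
    n <- sample(seq_len(floor(N / 2)), 1)
    exp_analytic <- rarefy_expected(counts, n)
    pool <- rep(seq_along(counts), counts)
    draws <- replicate(1e4, length(unique(sample(pool, n))))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(exp_analytic - mean(draws)), 3 * se + 1e-9)
  }
})

test_that("rarefaction curves are nondecreasing and end at observed richness", {
  run <- tiny_mock_run(depth = 2000, seed = 63)
  rc <- rarefaction_curve(run$otus)
  for (s in unique(rc$sample)) {
    y <- rc$expected_richness[rc$sample == s]
    expect_true(all(diff(y) >= -1e-9))
    expect_equal(y[length(y)], unname(richness(run$otus)[s]))
  }
})

test_that("median-depth normalization equalizes sample totals", {
  ot <- toy_otutab(cbind(S1 = c(60, 40), S2 = c(150, 50), S3 = c(200, 100)))
  norm <- median_depth_normalize(ot)
  expect_equal(unname(colSums(norm$counts)), rep(200, 3))
  # factors (2, 1, 2/3) against depths (100, 200, 300)
  expect_equal(unname(norm$counts[, "S1"] / ot$counts[, "S1"]), rep(2, 2))
  expect_equal(unname(norm$counts[, "S3"] / ot$counts[, "S3"]), rep(2 / 3, 2))
  # all-equal depths: identity; single sample: unchanged
  ot_eq <- toy_otutab(cbind(S1 = c(5, 5), S2 = c(4, 6)))
  expect_equal(median_depth_normalize(ot_eq)$counts, ot_eq$counts,
               tolerance = 1e-12, ignore_attr = TRUE)
  ot1 <- toy_otutab(cbind(S1 = c(7, 3)))
  expect_equal(median_depth_normalize(ot1)$counts, ot1$counts,
               ignore_attr = TRUE)
})

test_that("Bray-Curtis follows its definition and metric-like properties", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(6, 4), c(2, 8)), 0.4, tolerance = 1e-12)
  set.seed(64)
  for (k in 1:20) {
    x <- runif(6) * sample(1:10, 1)
    y <- runif(6) * sample(1:10, 1)
    d <- bray_curtis(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(y, x), tolerance = 1e-12)
    # hand formula
    expect_equal(d, 1 - 2 * sum(pmin(x, y)) / sum(x + y), tolerance = 1e-12)
  }
})

test_that("PCoA handles minimal and symmetric configurations", {
  d2 <- as.dist(matrix(c(0, 1, 1, 0), 2, 2))
  ord2 <- pcoa_ordination(d2)
  expect_identical(ncol(ord2$coordinates), 1L)
  expect_equal(ord2$variance_percent, 100)
  # three equidistant samples: two equal axes at 50% each
  d3 <- as.dist(matrix(1, 3, 3) - diag(3))
  ord3 <- pcoa_ordination(d3)
  expect_equal(ord3$variance_percent, c(50, 50), tolerance = 1e-9)
})

test_that("PCoA recovers planted Euclidean configurations up to rotation", {
  set.seed(65)
  X <- matrix(rnorm(20), ncol = 2)
  ord <- pcoa_ordination(dist(X), k = 2)
  expect_lt(procrustes_residual(X, ord$coordinates), 1e-8)
})

test_that("non-Euclidean distances trigger the negative-eigenvalue warning", {
  spec <- mock_preset("MC2", depth = 1500, seed = 66)
  refs <- make_reference_set(spec)
  sim <- simulate_reads(spec, refs, n_samples = 5)
  ot <- abundance_filter(suppressMessages(
    remove_chimeras(swarm_cluster(dereplicate(sim$reads)))))
  bc <- bray_curtis_matrix(ot)
  expect_true(all(as.matrix(bc) >= 0) && all(as.matrix(bc) <= 1))
  ord <- tryCatch(pcoa_ordination(bc), warning = function(w) {
    expect_match(conditionMessage(w), "negative eigenvalues")
    suppressWarnings(pcoa_ordination(bc))
  })
  expect_true(all(diff(ord$variance_percent) <= 1e-9))  # nonincreasing axes
})

test_that("composition tables are column-normalized fractions", {
  run <- tiny_mock_run("MC2", depth = 2500, seed = 67)
  comp <- composition_table(run$otus, run$assignments, "phylum")
  expect_equal(unname(colSums(comp)), rep(1, ncol(comp)), tolerance = 1e-9)
  expect_setequal(rownames(comp), c("Firmicutes", "Proteobacteria"))
})
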