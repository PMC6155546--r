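# Dereplication, swarm clustering, chimera removal, abundance filtering.

test_that("dereplication groups exact strings and conserves counts", {
  d <- dereplicate(list(S1 = c("AAA", "AAA", "AAT")))
  expect_identical(d$seqs, c("AAA", "AAT"))
  expect_identical(as.integer(d$counts), c(2L, 1L))
  expect_identical(length(dereplicate(list(S1 = character(0)))$seqs), 0L)
  d2 <- dereplicate(list(S1 = "ACGT", S2 = "ACGT"))
  expect_identical(unname(d2$counts[1, ]), c(1L, 1L))
  expect_identical(sum(d2$counts), 2L)
})

test_that("swarm clustering chains transitively at distance d", {
  # A-B at 3, B-C at 3, A-C at 6: one component
  A <- strrep("A", 30)
  B <- paste0(strrep("A", 27), "TTT")
  C <- paste0(strrep("A", 24), "TTTTTT")
  stopifnot(drop(adist(A, C)) == 6L)
  d <- dereplicate(list(S = c(rep(A, 5), rep(B, 3), C)))
  ot <- swarm_cluster(d, d = 3)
  expect_identical(nrow(ot$counts), 1L)
  expect_identical(unname(ot$representatives), A)  # most abundant member
  expect_setequal(ot$members$Cluster_1, c(A, B, C))
  # at distance 4 with d = 3: two OTUs
  D <- paste0(strrep("A", 26), "TTTT")
  ot2 <- swarm_cluster(dereplicate(list(S = c(A, D))), d = 3)
  expect_identical(nrow(ot2$counts), 2L)
  # single unique sequence: its own representative
  ot3 <- swarm_cluster(dereplicate(list(S = "ACGTACGT")), d = 3)
  expect_identical(unname(ot3$representatives), "ACGTACGT")
})

test_that("swarm clustering equals brute-force single-linkage components", {
  set.seed(33)
  for (rep_i in 1:5) {
    # seeds plus noisy satellites, up to 200 uniques
    n_seed <- sample(3:6, 1)
    seeds <- vapply(seq_len(n_seed), function(i) random_dna_str(60),
                    character(1))
    seqs <- seeds
    for (s in seeds) {
      nsat <- sample(5:15, 1)
      for (k in seq_len(nsat)) {
        ch <- strsplit(s, "")[[1]]
        nmut <- sample(1:5, 1)
        pos <- sample(length(ch), nmut)
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        seqs <- c(seqs, paste(ch, collapse = ""))
      }
    }
    seqs <- unique(seqs)
    reads <- rep(seqs, times = sample(1:4, length(seqs), replace = TRUE))
    derep <- dereplicate(list(S = reads))
    ot <- swarm_cluster(derep, d = 3)
    got <- character(0)
    for (id in names(ot$members))
      got <- c(got, paste(sort(ot$members[[id]]), collapse = ","))
    oracle_comp <- brute_force_components(derep$seqs, 3)
    expect_identical(paste(sort(got), collapse = ";"),
                     partition_signature(derep$seqs, oracle_comp))
  }
})

test_that("representatives are highest-count members with lexicographic ties", {
  a <- "AAAA"; b <- "AAAT"
  ot <- swarm_cluster(dereplicate(list(S = c(a, b))), d = 3)
  expect_identical(unname(ot$representatives), a)  # tie at 1 read each
  ot2 <- swarm_cluster(dereplicate(list(S = c(a, b, b))), d = 3)
  expect_identical(unname(ot2$representatives), b)
})

test_that("constructed chimeric OTUs are flagged and dropped", {
  set.seed(34)
  pA <- random_dna_str(280)
  pB <- random_dna_str(280)
  chim <- paste0(substr(pA, 1, 140), substr(pB, 141, 280))
  reads <- c(rep(pA, 50), rep(pB, 40), rep(chim, 4))
  ot <- swarm_cluster(dereplicate(list(S = reads)), d = 3)
  expect_identical(nrow(ot$counts), 3L)
  ot2 <- suppressMessages(remove_chimeras(ot))
  expect_identical(nrow(ot2$counts), 2L)
  expect_false(chim %in% ot2$representatives)
  expect_equal(attr(ot2, "chimera_removed_reads"), 4)
  # no two-parent decomposition: kept
  lone <- random_dna_str(280)
  ot3 <- suppressMessages(remove_chimeras(
    swarm_cluster(dereplicate(list(S = c(rep(pA, 50), rep(pB, 40), lone))),
                  d = 3)))
  expect_identical(nrow(ot3$counts), 3L)
})

test_that("chimeras with parents rarer than the query are kept", {
  set.seed(35)
  pA <- random_dna_str(280)
  pB <- random_dna_str(280)
  chim <- paste0(substr(pA, 1, 140), substr(pB, 141, 280))
  # query more abundant than both 'parents': abundance-order check over all
  # parent pairs says nothing qualifies
  reads <- c(rep(pA, 5), rep(pB, 4), rep(chim, 50))
  ot <- suppressMessages(remove_chimeras(
    swarm_cluster(dereplicate(list(S = reads)), d = 3)))
  expect_identical(nrow(ot$counts), 3L)
  # parents at exactly 2x qualify; just below do not
  reads2x <- c(rep(pA, 8), rep(pB, 8), rep(chim, 4))
  expect_identical(
    nrow(suppressMessages(remove_chimeras(
      swarm_cluster(dereplicate(list(S = reads2x)), d = 3)))$counts), 2L)
  reads_below <- c(rep(pA, 7), rep(pB, 8), rep(chim, 4))
  expect_identical(
    nrow(suppressMessages(remove_chimeras(
      swarm_cluster(dereplicate(list(S = reads_below)), d = 3)))$counts), 3L)
})

test_that("pre-clustering chimera removal stops single-linkage bridging", {
  set.seed(39)
  base <- random_dna_str(250)
  pA <- base
  pB <- gyrbench:::mutate_at(base, c(20, 60, 100, 140, 180, 200, 220, 240))
  stopifnot(drop(adist(pA, pB)) == 8L)
  # chimeras of the same parent pair at staggered breakpoints form a
  # stepping-stone path between the parents
  bridge <- vapply(c(80, 160, 210), function(bp)
    paste0(substr(pA, 1, bp), substr(pB, bp + 1, 250)), character(1))
  reads <- list(S = c(rep(pA, 300), rep(pB, 150), rep(bridge, each = 2)))
  merged <- swarm_cluster(dereplicate(reads), d = 3)
  expect_identical(nrow(merged$counts), 1L)  # the failure mode
  kept <- suppressMessages(cluster_reads(reads, min_total = 2))
  expect_identical(nrow(kept$counts), 2L)
  expect_setequal(unname(kept$representatives), c(pA, pB))
  expect_equal(attr(kept, "chimera_removed_reads"), 6)
})

test_that("the abundance filter keeps totals of 11+ (strictly more than 10)", {
  set.seed(36)
  seqs <- vapply(1:3, function(i) random_dna_str(60), character(1))
  reads <- c(rep(seqs[1], 11), rep(seqs[2], 10), rep(seqs[3], 500))
  ot <- swarm_cluster(dereplicate(list(S = reads)), d = 3)
  kept <- abundance_filter(ot, min_total = 11)
  expect_identical(sort(unname(rowSums(kept$counts))), c(11, 500))
  expect_identical(attr(kept, "filter_removed_reads"), 10)
  # threshold 0 is the identity
  expect_identical(nrow(abundance_filter(ot, min_total = 0)$counts), 3L)
  # everything below threshold: empty table with a warning, not an error
  expect_warning(empty <- abundance_filter(ot, min_total = 1000), "below")
  expect_identical(nrow(empty$counts), 0L)
})

test_that("read counts are conserved across the pipeline ledger", {
  run <- tiny_mock_run(depth = 5000, seed = 37)
  ot <- run$otus
  total_out <- sum(ot$counts) + attr(ot, "chimera_removed_reads") +
    attr(ot, "filter_removed_reads")
  expect_identical(as.integer(total_out), 5000L)
})

test_that("error-free well-separated references give exactly the expected OTU count", {
  spec <- mock_preset("MC4", depth = 20000, error_rate = 0, chimera_rate = 0,
                      seed = 38)
  refs <- make_reference_set(spec)
  sim <- simulate_reads(spec, refs)
  ot <- swarm_cluster(dereplicate(sim$reads), d = 3)
  # expected components: merge strains at distance <= 3 within each
  # (species, gene); oracle on the reference sequences themselves
  oracle <- max(brute_force_components(refs$sequence, 3))
  expect_identical(nrow(ot$counts), oracle)
  # gyrB: L. sakei 2 + B. thermosphacta 1 + L. gelidum 2 + P. lundensis 3 +
  # S. proteamaculans 3 = 11; parE adds L. sakei 2 + B. thermosphacta 1 +
  # L. gelidum 2 = 5
  expect_identical(nrow(ot$counts), 16L)
})
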