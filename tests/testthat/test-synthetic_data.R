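# Mock-community generator: reference divergence plans, read simulation and
# qPCR emulation.

test_that("mock presets encode the published compositions", {
  for (nm in c("MC1", "MC2", "MC3", "MC4")) {
    spec <- mock_preset(nm)
    expect_equal(sum(spec$members$proportion), 1, tolerance = 1e-12)
  }
  expect_identical(nrow(mock_preset("MC1")$members), 15L)
  expect_identical(nrow(mock_preset("MC4")$members), 14L)
  expect_identical(length(unique(mock_preset("MC4")$members$species)), 5L)
  # phylum splits 99/1, 50/50, 1/99, 65/35
  firm_frac <- function(spec) {
    tab <- gyrbench:::mock_strain_table()$tax
    phyla <- vapply(spec$members$species, function(s) tab[[s]][["phylum"]],
                    character(1))
    sum(spec$members$proportion[phyla == "Firmicutes"])
  }
  expect_equal(firm_frac(mock_preset("MC1")), 0.99, tolerance = 1e-12)
  expect_equal(firm_frac(mock_preset("MC2")), 0.50, tolerance = 1e-12)
  expect_equal(firm_frac(mock_preset("MC3")), 0.01, tolerance = 1e-12)
  expect_equal(firm_frac(mock_preset("MC4")), 0.65, tolerance = 1e-12)
})

test_that("reference sets realize the planned strain divergences (edit-distance oracle)", {
  spec <- mock_preset("MC4", seed = 5)
  refs <- make_reference_set(spec)
  plan <- default_divergence_plan()
  for (sp in names(plan)) {
    dm <- plan[[sp]]
    ids <- rownames(dm)
    ids <- ids[ids %in% refs$strain[refs$species == sp]]
    if (length(ids) < 2) next
    seqs <- vapply(ids, function(st)
      refs$sequence[refs$species == sp & refs$strain == st &
                    refs$gene == "gyrB"], character(1))
    got <- adist(seqs, seqs)
    expect_equal(unname(got), unname(dm[ids, ids]),
                 ignore_attr = TRUE, label = sp)
  }
  # the published L. sakei plan: 23K ~ DSM15831 at 2, DSM20017 at 8 from both
  ls <- refs[refs$species == "Lactobacillus sakei" & refs$gene == "gyrB", ]
  s <- setNames(ls$sequence, ls$strain)
  expect_equal(drop(adist(s[["23K"]], s[["DSM15831"]])), 2, ignore_attr = TRUE)
  expect_equal(drop(adist(s[["23K"]], s[["DSM20017"]])), 8, ignore_attr = TRUE)
  expect_equal(drop(adist(s[["DSM15831"]], s[["DSM20017"]])), 8, ignore_attr = TRUE)
})

test_that("identical planned distance 0 yields identical sequences; Proteobacteria get no parE", {
  spec <- mock_preset("MC4", seed = 6)
  plan <- default_divergence_plan()
  plan[["Serratia proteamaculans"]][] <- 0L
  refs <- make_reference_set(spec, divergence_plan = plan)
  se <- refs$sequence[refs$species == "Serratia proteamaculans"]
  expect_true(all(se == se[1]))
  # no parE emitted outside Firmicutes
  tab <- gyrbench:::mock_strain_table()$tax
  phyla <- vapply(refs$species, function(x) tab[[x]][["phylum"]], character(1))
  expect_true(all(phyla[refs$gene == "parE"] == "Firmicutes"))
  # parE far from every gyrB (>= 20% of length)
  gy <- refs$sequence[refs$gene == "gyrB"]
  pa <- refs$sequence[refs$gene == "parE"]
  expect_true(min(adist(pa, gy)) >= 0.2 * 250)
})

test_that("unrealizable divergence plans error", {
  spec <- mock_preset("MC4", seed = 7)
  plan <- default_divergence_plan()
  plan[["Lactobacillus sakei"]][] <- c(0, 1, 10, 1, 0, 1, 10, 1, 0)  # violates triangle
  expect_error(make_reference_set(spec, divergence_plan = plan),
               "unrealizable")
})

test_that("error-free, chimera-free reads equal their references and counts conserve depth", {
  spec <- mock_preset("MC1", depth = 3000, error_rate = 0, chimera_rate = 0,
                      seed = 8)
  refs <- make_reference_set(spec)
  sim <- simulate_reads(spec, refs)
  expect_identical(length(sim$reads$MC1), 3000L)
  expect_true(all(sim$reads$MC1 %in% refs$sequence))
  expect_identical(sum(sim$truth$count), 3000L)
  expect_error(simulate_reads(spec, refs[0, ]), "empty reference")
})

test_that("phylum and paralog read fractions follow the multinomial model", {
  depth <- 100000
  spec <- mock_preset("MC1", depth = depth, error_rate = 0, chimera_rate = 0,
                      seed = 9)
  refs <- make_reference_set(spec)
  sim <- simulate_reads(spec, refs)
  tab <- gyrbench:::mock_strain_table()$tax
  phyla <- vapply(sim$truth$species, function(s) tab[[s]][["phylum"]],
                  character(1))
  firm <- sum(sim$truth$count[phyla == "Firmicutes"]) / depth
  sd3 <- 3 * sqrt(0.99 * 0.01 / depth)
  expect_lt(abs(firm - 0.99), sd3)
  # L. algidus: ~80% of its reads are parE
  la <- sim$truth[sim$truth$species == "Lactobacillus algidus", ]
  frac_pare <- sum(la$count[la$gene == "parE"]) / sum(la$count)
  n_la <- sum(la$count)
  expect_lt(abs(frac_pare - 0.8), 3 * sqrt(0.8 * 0.2 / n_la))
})

test_that("substitution errors hit at the configured rate", {
  spec <- mock_preset("MC1", depth = 20000, error_rate = 2e-3,
                      chimera_rate = 0, seed = 10)
  refs <- make_reference_set(spec)
  sim <- simulate_reads(spec, refs)
  # mean edits per read vs closest reference: binomial(L, e) expectation
  reads <- sim$reads$MC1
  u <- unique(reads)
  dmin <- apply(adist(u, refs$sequence), 1, min)
  mean_err <- sum(dmin[match(reads, u)]) / length(reads)
  L <- nchar(refs$sequence[1])
  expected <- L * 2e-3
  expect_lt(abs(mean_err - expected), 4 * sqrt(expected / length(reads)))
})

test_that("chimeras join a prefix and suffix of two distinct references", {
  spec <- mock_preset("MC2", depth = 5000, error_rate = 0, chimera_rate = 0.05,
                      seed = 11)
  refs <- make_reference_set(spec)
  sim <- simulate_reads(spec, refs)
  n_chim <- sim$truth$count[sim$truth$gene == "chimera"]
  expect_gt(n_chim, 0)
  nonref <- setdiff(sim$reads$MC2, refs$sequence)
  expect_gt(length(nonref), 0)
  # each non-reference read decomposes as prefix of one ref + suffix of another
  check <- vapply(head(nonref, 20), function(ch) {
    L <- nchar(ch)
    for (bp in 1:(L - 1)) {
      pre_ok <- any(substr(refs$sequence, 1, bp) == substr(ch, 1, bp))
      suf_ok <- any(substr(refs$sequence, nchar(refs$sequence) - (L - bp) + 1,
                           nchar(refs$sequence)) == substr(ch, bp + 1, L))
      if (pre_ok && suf_ok) return(TRUE)
    }
    FALSE
  }, logical(1))
  expect_true(all(check))
})

test_that("simulation is byte-deterministic under a fixed seed", {
  spec <- mock_preset("MC1", depth = 1000, seed = 12)
  refs1 <- make_reference_set(spec)
  refs2 <- make_reference_set(spec)
  expect_identical(refs1, refs2)
  s1 <- simulate_reads(spec, refs1)
  s2 <- simulate_reads(spec, refs1)
  expect_identical(s1, s2)
  d1 <- tempfile(); d2 <- tempfile()
  write_read_fasta(s1$reads, d1, seed = 12)
  write_read_fasta(s2$reads, d2, seed = 12)
  expect_identical(readLines(file.path(d1, "MC1.fasta")),
                   readLines(file.path(d2, "MC1.fasta")))
})

test_that("simulated qPCR matches the calibration curves in closed form", {
  cfu <- data.frame(sample = "S1", species = c("a", "b"), cfu = c(1, exp(1)))
  attr(cfu, "total_cfu") <- 1
  qp <- simulate_qpcr(cfu, noise_sd = 0, seed = 1)
  hk <- qp[qp$species != "all_bacteria", ]
  expect_equal(hk$Ct[hk$species == "a"], 40.98, tolerance = 1e-12)
  expect_equal(hk$Ct[hk$species == "b"], 40.98 - 1.44, tolerance = 1e-12)
  allb <- qp[qp$species == "all_bacteria", ]
  expect_equal(allb$Ct, 39.43, tolerance = 1e-12)
  expect_error(simulate_qpcr(data.frame(sample = "S", species = "x", cfu = 0)),
               "positive")
  # round trip: ct_to_cfu inverts the noiseless simulation to 1e-9 relative
  loads <- 10^seq(0, 8, by = 0.5)
  cf <- data.frame(sample = "S", species = paste0("sp", seq_along(loads)),
                   cfu = loads)
  qp2 <- simulate_qpcr(cf, noise_sd = 0, seed = 2)
  back <- ct_to_cfu(qp2$Ct, calibration_curve("housekeeping"))
  expect_equal(back, loads, tolerance = 1e-9)
})
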