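# Shared helpers: independent oracles and small fixture builders.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force single-linkage components at edit distance <= d, via the
# full adist matrix and repeated set expansion. Independent of the
# package's clustering path.
brute_force_components <- function(seqs, d) {
  n <- length(seqs)
  dm <- adist(seqs, seqs)
  adj <- dm <= d
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cid <- cid + 1L
    members <- i
    repeat {
      grow <- which(comp == 0L & apply(adj[, members, drop = FALSE], 1L, any))
      grow <- setdiff(grow, members)
      if (!length(grow)) break
      members <- c(members, grow)
    }
    comp[members] <- cid
  }
  comp
}

# canonical partition signature (order-independent) for comparing clusterings
partition_signature <- function(seqs, comp) {
  groups <- split(seqs, comp)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, character(1L), collapse = ",")),
        collapse = ";")
}

# a small fully deterministic mock run shared by several test files
tiny_mock_run <- function(preset = "MC1", depth = 4000, seed = 42,
                          error_rate = 1e-3, chimera_rate = 0.01) {
  spec <- mock_preset(preset, depth = depth, seed = seed,
                      error_rate = error_rate, chimera_rate = chimera_rate)
  refs <- make_reference_set(spec)
  sim <- simulate_reads(spec, refs)
  otus <- suppressMessages(cluster_reads(sim$reads))
  db <- build_database(markers_as_genome_records(refs))
  assignments <- suppressMessages(assign_taxonomy(otus, db))
  list(spec = spec, refs = refs, sim = sim, otus = otus, db = db,
       assignments = assignments)
}

# orthogonal-Procrustes residual after optimal translation/rotation/
# reflection/scaling of Y onto X (independent check for PCoA round trips)
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)
  scale_fac <- sum(s$d) / sum(Yc^2)
  sum((Xc - scale_fac * Yc %*% R)^2)
}
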