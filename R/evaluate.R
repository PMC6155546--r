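## Truth-vs-observed scoring of a mock-community run: composition recovery,
## richness recovery, paralog-ratio recovery and strain-cluster resolution.

# truth table aggregated at a rank (chimera rows excluded)
truth_fractions <- function(truth, rank) {
  tr <- truth[truth$gene != "chimera", , drop = FALSE]
  tab <- mock_strain_table()$tax
  taxon <- if (rank == "species") tr$species
           else vapply(tr$species, function(s) tab[[s]][[rank]], character(1L))
  agg <- rowsum(tr$count, group = paste(tr$sample, taxon, sep = "\r"))
  key <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(sample = vapply(key, `[`, character(1L), 1L),
                    taxon = vapply(key, `[`, character(1L), 2L),
                    count = agg[, 1L], stringsAsFactors = FALSE)
  tot <- tapply(out$count, out$sample, sum)
  out$fraction <- out$count / tot[out$sample]
  rownames(out) <- NULL
  out
}

#' Composition recovery: observed vs expected taxon fractions
#'
#' Observed fractions are computed from assigned reads (post chimera removal
#' and abundance filtering); expected fractions come from the generator's
#' truth table (chimeric reads excluded). The tolerance column is
#' `max(min_tol, 3 * binomial SD)` at the sample's assigned depth.
#'
#' @param truth truth table from [simulate_reads()].
#' @param assignments [assign_taxonomy()] output.
#' @param otus the filtered `otutab`.
#' @param rank taxonomy rank (default `"phylum"`).
#' @param min_tol floor of the tolerance band (default 0.02).
#' @return `data.frame(sample, taxon, expected, observed, difference,
#'   tolerance, within_tolerance)`.
#' @export
composition_recovery <- function(truth, assignments, otus, rank = "phylum",
                                 min_tol = 0.02) {
  obs_tab <- composition_table(otus, assignments, rank)
  exp_tab <- truth_fractions(truth, rank)
  samples <- colnames(obs_tab)
  rows <- list()
  for (s in samples) {
    n_assigned <- sum(merge_by_rank(otus, assignments, rank)[, s])
    taxa <- union(rownames(obs_tab)[obs_tab[, s] > 0],
                  exp_tab$taxon[exp_tab$sample == s & exp_tab$fraction > 0])
    for (tx in sort(taxa)) {
      e <- exp_tab$fraction[exp_tab$sample == s & exp_tab$taxon == tx]
      e <- if (length(e)) e else 0
      o <- if (tx %in% rownames(obs_tab)) obs_tab[tx, s] else 0
      tol <- max(min_tol, 3 * sqrt(e * (1 - e) / max(n_assigned, 1)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, taxon = tx, expected = e, observed = o,
        difference = abs(o - e), tolerance = tol,
        within_tolerance = abs(o - e) <= tol, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Richness recovery: observed vs truth-derived taxon counts
#'
#' @param truth truth table from [simulate_reads()].
#' @param otus filtered `otutab`.
#' @param assignments [assign_taxonomy()] output.
#' @param ranks taxonomy ranks to score (default species and genus).
#' @return `data.frame(sample, rank, expected, observed)`.
#' @export
richness_recovery <- function(truth, otus, assignments,
                              ranks = c("species", "genus")) {
  tab <- mock_strain_table()$tax
  tr <- truth[truth$gene != "chimera", , drop = FALSE]
  rows <- list()
  for (rk in ranks) {
    obs <- richness(otus, rank = rk, assignments = assignments)
    for (s in unique(tr$sample)) {
      sp <- unique(tr$species[tr$sample == s & tr$count > 0])
      expd <- if (rk == "species") length(sp)
              else length(unique(vapply(sp, function(x) tab[[x]][[rk]],
                                        character(1L))))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, rank = rk, expected = expd,
        observed = unname(obs[s]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Strain-cluster resolution for one species
#'
#' Lists the OTUs assigned to a species with each OTU's fraction of the
#' species' reads (optionally within one gene label), and cross-references
#' each OTU to its nearest reference strain(s) by representative-to-reference
#' edit distance.
#'
#' @param otus filtered `otutab`.
#' @param assignments [assign_taxonomy()] output.
#' @param species species name.
#' @param refs reference `marker_db` (for strain cross-referencing);
#'   optional.
#' @param gene restrict to one gene label (`"gyrB"`/`"parE"`); `NULL` for
#'   all.
#' @return `data.frame(otu_id, gene, reads, fraction, strains)`; zero rows
#'   when the species is absent.
#' @export
strain_resolution <- function(otus, assignments, species, refs = NULL,
                              gene = NULL) {
  a <- assignments[match(rownames(otus$counts), assignments$otu_id), ]
  sel <- !is.na(a$species) & a$species == species
  if (!is.null(gene)) sel <- sel & a$gene == gene
  if (!any(sel)) return(data.frame(otu_id = character(), gene = character(),
                                   reads = numeric(), fraction = numeric(),
                                   strains = character()))
  counts <- rowSums(otus$counts[sel, , drop = FALSE])
  reps <- otus$representatives[sel]
  total <- sum(counts)
  strains <- rep(NA_character_, length(reps))
  if (!is.null(refs)) {
    rsel <- refs$species == species
    if (!is.null(gene)) rsel <- rsel & refs$gene == gene
    rsub <- refs[rsel, , drop = FALSE]
    if (nrow(rsub)) {
      dm <- adist(reps, rsub$sequence)
      # every strain whose reference would fall in this OTU (distance <= d),
      # or the nearest strain when none does
      strains <- apply(dm, 1L, function(dr) {
        hit <- dr <= max(min(dr), otus$d)
        paste(sort(rsub$strain[hit]), collapse = ",")
      })
    }
  }
  out <- data.frame(otu_id = names(reps), gene = a$gene[sel], reads = counts,
                    fraction = counts / total, strains = strains,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$reads), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paralog-ratio recovery against the generator truth
#'
#' Compares each species' observed gyrB read fraction with `1 -
#' pare_fraction` from the mock specification, with a 3-binomial-SD
#' tolerance (floored at `min_tol`).
#'
#' @param spec the [mock_spec()] that generated the data.
#' @param assignments,otus pipeline outputs.
#' @param min_tol tolerance floor (default 0.02).
#' @return `data.frame(species, expected_gyrb, observed_gyrb, n_reads,
#'   tolerance, within_tolerance)`.
#' @export
paralog_recovery <- function(spec, assignments, otus, min_tol = 0.02) {
  pr <- paralog_ratios(assignments, otus, rank = "species")
  rows <- lapply(seq_len(nrow(pr)), function(i) {
    sp <- pr$taxon[i]
    pf <- spec$pare_fraction[[sp]]
    if (is.null(pf) || is.na(pf)) return(NULL)
    a <- assignments[match(rownames(otus$counts), assignments$otu_id), ]
    sel <- !is.na(a$species) & a$species == sp & a$gene %in% c("gyrB", "parE")
    n <- sum(otus$counts[sel, , drop = FALSE])
    e <- 1 - pf
    tol <- max(min_tol, 3 * sqrt(e * (1 - e) / max(n, 1)))
    data.frame(species = sp, expected_gyrb = e,
               observed_gyrb = pr$mean_gyrb_fraction[i], n_reads = n,
               tolerance = tol,
               within_tolerance = abs(pr$mean_gyrb_fraction[i] - e) <= tol,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
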