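## Synthetic reference sequences, mock-community reads and matched qPCR
## measurements. Everything downstream of wet-lab sequencing is emulated:
## the generator emits merged, primer-trimmed reads with substitution errors
## and optional two-parent chimeras, plus threshold-cycle values consistent
## with the package's calibration curves.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

# substitute the bases at `pos` with different, random bases
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

# mutate a fraction `rate` of positions (used to carve species/paralog
# divergence out of common ancestral sequences)
diverge <- function(seq, rate) {
  L <- nchar(seq)
  k <- max(1L, round(rate * L))
  mutate_at(seq, sample.int(L, k))
}

#' Default intra-species divergence plan for the MC4 strains
#'
#' Pairwise edit distances between strains of the same species, realizable as
#' a star metric. The Lactobacillus sakei plan keeps 23K and DSM15831 within
#' the clustering radius (distance 2) and DSM20017 outside it (distance 8 to
#' both); Brochothrix thermosphacta strains are near-clonal (pairwise 2); the
#' two Leuconostoc gelidum subspecies sit 12 apart; Pseudomonas lundensis and
#' Serratia proteamaculans strains are pairwise 6 apart.
#'
#' @return named list: species -> symmetric integer distance matrix with
#'   strain ids as dimnames.
#' @export
default_divergence_plan <- function() {
  pairwise <- function(ids, d) {
    m <- matrix(d, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 0L
    m
  }
  sakei <- matrix(c(0, 8, 2,
                    8, 0, 8,
                    2, 8, 0), 3, 3,
                  dimnames = list(c("23K", "DSM20017", "DSM15831"),
                                  c("23K", "DSM20017", "DSM15831")))
  list(
    "Lactobacillus sakei" = sakei,
    "Brochothrix thermosphacta" = pairwise(c("160x8", "cH814", "ATCC11509"), 2L),
    "Leuconostoc gelidum" = pairwise(c("MFPA44A14-01", "DSM5578"), 12L),
    "Pseudomonas lundensis" = pairwise(c("MFPA15A12-05", "MFPB42A12-09", "PCAi-D2.2"), 6L),
    "Serratia proteamaculans" = pairwise(c("MFPA44A14-05", "1C2F", "CIP103236"), 6L)
  )
}

# Solve a star-metric realization: per-strain substitution budgets m_i with
# d(i,j) = m_i + m_j, substitutions applied at disjoint positions. Errors
# when the plan is not expressible this way.
star_budgets <- function(dm) {
  ids <- rownames(dm)
  k <- length(ids)
  if (k == 1L) return(setNames(0L, ids))
  if (k == 2L) {
    d <- dm[1L, 2L]
    return(setNames(c(floor(d / 2), ceiling(d / 2)), ids))
  }
  m <- numeric(k)
  for (i in seq_len(k)) {
    oth <- setdiff(seq_len(k), i)
    j <- oth[1L]; l <- oth[2L]
    m[i] <- (dm[i, j] + dm[i, l] - dm[j, l]) / 2
  }
  recon <- outer(m, m, `+`); diag(recon) <- 0
  if (any(m < 0) || any(m != round(m)) || any(abs(recon - dm) > 1e-9))
    stop("unrealizable divergence plan for strains ",
         paste(ids, collapse = ", "), call. = FALSE)
  setNames(as.integer(m), ids)
}

#' Generate synthetic marker references for a mock community
#'
#' Emits one gyrB amplicon reference per strain and, for Firmicutes species
#' with a positive parE fraction, one parE reference per strain. Sequences
#' are drawn hierarchically (phylum ancestor -> species -> strain) so that
#' species are far apart, intra-species strains differ by exactly the
#' planned edit distances, and every parE sequence differs from every gyrB
#' sequence by at least 20% of its length — mirroring the observed paralog
#' phylogeny in which Firmicutes parE is closer to Firmicutes gyrB than
#' Proteobacteria gyrB is.
#'
#' @param spec a [mock_spec()].
#' @param divergence_plan named list of per-species strain distance matrices
#'   (see [default_divergence_plan()]); species absent from the plan get
#'   identical strain sequences.
#' @param length amplicon insert length in nt.
#' @param seed integer seed (defaults to the spec's).
#' @return a `marker_db` data.frame (one row per reference amplicon).
#' @export
make_reference_set <- function(spec, divergence_plan = default_divergence_plan(),
                               length = 250L, seed = spec$seed) {
  stopifnot(inherits(spec, "mock_spec"))
  set.seed(seed)
  tab <- mock_strain_table()$tax
  species <- unique(spec$members$species)
  phyla <- vapply(species, function(s) tab[[s]][["phylum"]], character(1L))
  # one root, phylum ancestors and a parE ancestor at calibrated offsets:
  # Firmicutes parE ends up closer to Firmicutes gyrB (~52% identity) than
  # Proteobacteria gyrB is (~48%), and no pairwise divergence approaches
  # K2P saturation
  root <- random_dna(length)
  anc <- lapply(unique(phyla), function(p)
    diverge(root, if (p == "Firmicutes") 0.15 else 0.30))
  names(anc) <- unique(phyla)
  pare_anc <- if ("Firmicutes" %in% phyla) diverge(root, 0.25)
  rows <- list()
  for (s in species) {
    strains <- spec$members$strain_id[spec$members$species == s]
    base_gyrb <- diverge(anc[[phyla[[s]]]], 0.10)
    pf <- spec$pare_fraction[[s]]
    base_pare <- if (pf > 0) diverge(pare_anc, 0.10)
    dm <- divergence_plan[[s]]
    budgets <- if (is.null(dm)) setNames(rep(0L, length(strains)), strains)
               else {
                 if (!all(strains %in% rownames(dm)))
                   stop("divergence plan lacks strains of ", s, call. = FALSE)
                 star_budgets(dm[strains, strains, drop = FALSE])
               }
    # disjoint substitution positions per strain
    need <- sum(budgets)
    if (need > length) stop("unrealizable divergence plan for ", s, call. = FALSE)
    pool <- sample.int(length, need)
    off <- 0L
    for (st in strains) {
      b <- budgets[[st]]
      pos <- if (b > 0) pool[(off + 1L):(off + b)] else integer()
      off <- off + b
      tax <- member_taxonomy(s, st)
      g <- if (b > 0) mutate_at(base_gyrb, pos) else base_gyrb
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = paste0(st, "_gyrB"), gene = "gyrB", t(tax),
        sequence = g, stringsAsFactors = FALSE)
      if (pf > 0) {
        p <- if (b > 0) mutate_at(base_pare, pos) else base_pare
        rows[[length(rows) + 1L]] <- data.frame(
          marker_id = paste0(st, "_parE"), gene = "parE", t(tax),
          sequence = p, stringsAsFactors = FALSE)
      }
    }
  }
  db <- do.call(rbind, rows)
  rownames(db) <- NULL
  class(db) <- c("marker_db", "data.frame")
  # paralog separation guard: every parE >= 20% of length from every gyrB
  gy <- db$sequence[db$gene == "gyrB"]
  pa <- db$sequence[db$gene == "parE"]
  if (length(pa)) {
    dmin <- min(adist(pa, gy))
    if (dmin < 0.2 * length)
      stop("paralog divergence guard failed (min distance ", dmin, ")",
           call. = FALSE)
  }
  db
}

#' Re-attach primers to marker amplicons, yielding genome records
#'
#' Wraps each stored insert with one concrete realization of the degenerate
#' primer pair, so that [build_database()] applied to the result reproduces
#' the marker database (a round-trip used by tests and by the end-to-end
#' pipeline, which assigns reads against a database rebuilt from these
#' records).
#'
#' @param db a `marker_db`.
#' @param primers a [primer_pair()].
#' @return list of [genome_record()] objects, one per marker row.
#' @export
markers_as_genome_records <- function(db, primers = primer_preset("gyrB")) {
  fwd <- concretize_primer(primers$forward)
  rev_site <- concretize_primer(revcomp(primers$reverse))
  lapply(seq_len(nrow(db)), function(i) {
    tax <- unlist(db[i, c(TAX_RANKS, "strain")])
    genome_record(
      record_id = sub(paste0("_", db$gene[i], "$"), "", db$marker_id[i]),
      taxonomy = tax,
      genes = data.frame(gene = db$gene[i],
                         sequence = paste0(fwd, db$sequence[i], rev_site)))
  })
}

#' Simulate mock-community amplicon reads with a matched truth table
#'
#' Read counts per (strain, gene) are multinomial with probability
#' proportional to the strain proportion times the gene split
#' (`pare_fraction` vs its complement). Each read copies its reference with
#' i.i.d. substitutions at `error_rate`; a `chimera_rate` fraction of reads
#' is replaced by two-parent chimeras joined at a uniform breakpoint (then
#' subjected to the same error process). Deterministic under a fixed seed.
#'
#' @param spec a [mock_spec()].
#' @param refs a `marker_db` from [make_reference_set()].
#' @param n_samples number of replicate samples to draw.
#' @param seed integer seed (defaults to the spec's).
#' @return list with `reads` (named list: sample -> character vector),
#'   `truth` (`data.frame(sample, strain_id, species, gene, count)`; chimeras
#'   carry `gene = "chimera"`), and `cfu`
#'   (`data.frame(sample, species, cfu)` plus attribute `total_cfu`).
#' @export
simulate_reads <- function(spec, refs, n_samples = 1L, seed = spec$seed) {
  stopifnot(inherits(spec, "mock_spec"))
  if (!nrow(refs)) stop("empty reference set", call. = FALSE)
  set.seed(seed)
  mem <- spec$members
  # per-(strain, gene) sampling weights
  pf <- spec$pare_fraction[mem$species]
  w <- data.frame(
    strain_id = c(mem$strain_id, mem$strain_id),
    species = c(mem$species, mem$species),
    gene = rep(c("gyrB", "parE"), each = nrow(mem)),
    prob = c(mem$proportion * (1 - pf), mem$proportion * pf),
    stringsAsFactors = FALSE)
  w <- w[w$prob > 0, , drop = FALSE]
  key <- paste(refs$strain, refs$gene)
  ref_of <- match(paste(w$strain_id, w$gene), key)
  if (anyNA(ref_of))
    stop("reference set lacks sequences for: ",
         paste(paste(w$strain_id, w$gene)[is.na(ref_of)], collapse = ", "),
         call. = FALSE)
  samples <- if (n_samples == 1L) spec$name
             else paste0(spec$name, "_s", seq_len(n_samples))
  reads <- list()
  truth <- list()
  for (si in seq_len(n_samples)) {
    n_chim <- rbinom(1L, spec$depth, spec$chimera_rate)
    n_real <- spec$depth - n_chim
    counts <- as.integer(rmultinom(1L, n_real, w$prob))
    template <- rep(refs$sequence[ref_of], counts)
    # chimeras: two distinct parents drawn by abundance, uniform breakpoint
    if (n_chim > 0L) {
      pa <- sample(nrow(w), n_chim, replace = TRUE, prob = w$prob)
      pb <- vapply(pa, function(a) {
        repeat {
          b <- sample(nrow(w), 1L, prob = w$prob)
          if (b != a) return(b)
        }
      }, integer(1L))
      sa <- refs$sequence[ref_of[pa]]
      sb <- refs$sequence[ref_of[pb]]
      bp <- vapply(sa, function(x) sample(nchar(x) - 1L, 1L), integer(1L),
                   USE.NAMES = FALSE)
      chim <- substr(sa, 1L, bp)
      chim <- paste0(chim, substr(sb, nchar(sb) - (nchar(sa) - bp) + 1L,
                                  nchar(sb)))
      template <- c(template, chim)
    }
    out_reads <- add_substitution_errors(template, spec$error_rate)
    reads[[samples[si]]] <- out_reads
    tr <- data.frame(sample = samples[si],
                     strain_id = rep(w$strain_id, counts),
                     species = rep(w$species, counts),
                     gene = rep(w$gene, counts), stringsAsFactors = FALSE)
    tr <- as.data.frame(table(strain_id = tr$strain_id, species = tr$species,
                              gene = tr$gene), stringsAsFactors = FALSE)
    names(tr)[names(tr) == "Freq"] <- "count"
    tr <- tr[tr$count > 0, , drop = FALSE]
    tr$sample <- samples[si]
    if (n_chim > 0L)
      tr <- rbind(tr, data.frame(strain_id = NA_character_,
                                 species = NA_character_, gene = "chimera",
                                 count = n_chim, sample = samples[si]))
    truth[[si]] <- tr[, c("sample", "strain_id", "species", "gene", "count")]
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  sp_prop <- tapply(mem$proportion, mem$species, sum)
  cfu <- expand.grid(sample = samples, species = names(sp_prop),
                     stringsAsFactors = FALSE)
  cfu$cfu <- spec$total_cfu * sp_prop[cfu$species]
  attr(cfu, "total_cfu") <- spec$total_cfu
  list(reads = reads, truth = truth, cfu = cfu)
}

# i.i.d. per-base substitutions at `rate` over a character vector of reads
add_substitution_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads)
  nerr <- rbinom(length(reads), L, rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    reads[i] <- mutate_at(reads[i], sample.int(L[i], nerr[i]))
  }
  reads
}

#' qPCR calibration curves
#'
#' Threshold cycle relates to load as `Ct = intercept + slope * ln(CFU)`,
#' equivalently `CFU = exp((Ct - intercept) / slope)`. The 16S probe curve
#' has intercept 39.43 and slope -1.52; the housekeeping-gene probe curve has
#' intercept 40.98 and slope -1.44.
#'
#' @param type `"16S"` or `"housekeeping"`.
#' @return list with `id`, `intercept` (Ct units) and `slope`
#'   (Ct per ln CFU.g^-1, negative).
#' @export
calibration_curve <- function(type = c("16S", "housekeeping")) {
  type <- match.arg(type)
  switch(type,
    "16S" = list(id = "16S", intercept = 39.43, slope = -1.52),
    housekeeping = list(id = "housekeeping", intercept = 40.98, slope = -1.44))
}

#' Simulate qPCR threshold cycles from true loads
#'
#' Per-species measurements use the housekeeping curve; one `all_bacteria`
#' measurement per sample (total load) uses the 16S curve. Gaussian noise of
#' `noise_sd` Ct units is added; with `noise_sd = 0` the simulation is the
#' exact inverse of [ct_to_cfu()].
#'
#' @param cfu `data.frame(sample, species, cfu)` with attribute `total_cfu`,
#'   as returned by [simulate_reads()], or any such frame.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed integer seed.
#' @param species optional subset of species to measure (the qPCR probe
#'   panel); default all.
#' @return `data.frame(sample, species, Ct, curve_id)`; the total-load rows
#'   have `species = "all_bacteria"`.
#' @export
simulate_qpcr <- function(cfu, noise_sd = 0.5, seed = 1L, species = NULL) {
  if (any(cfu$cfu <= 0)) stop("CFU loads must be positive", call. = FALSE)
  set.seed(seed)
  if (!is.null(species)) cfu <- cfu[cfu$species %in% species, , drop = FALSE]
  hk <- calibration_curve("housekeeping")
  uni <- calibration_curve("16S")
  out <- data.frame(sample = cfu$sample, species = cfu$species,
                    Ct = hk$intercept + hk$slope * log(cfu$cfu) +
                      rnorm(nrow(cfu), 0, noise_sd),
                    curve_id = hk$id, stringsAsFactors = FALSE)
  total <- attr(cfu, "total_cfu")
  if (!is.null(total)) {
    samples <- unique(cfu$sample)
    out <- rbind(out, data.frame(
      sample = samples, species = "all_bacteria",
      Ct = uni$intercept + uni$slope * log(total) +
        rnorm(length(samples), 0, noise_sd),
      curve_id = uni$id, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Write simulated reads as per-sample FASTA files
#'
#' @param reads named list: sample -> character vector of reads.
#' @param dir output directory.
#' @param seed seed recorded in each FASTA header line comment.
#' @return character vector of file paths, invisibly.
#' @export
write_read_fasta <- function(reads, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in names(reads)) {
    xs <- Biostrings::DNAStringSet(reads[[s]])
    names(xs) <- sprintf("%s_read%06d%s", s, seq_along(xs),
                         if (is.null(seed)) "" else paste0(" seed=", seed))
    p <- file.path(dir, paste0(s, ".fasta"))
    Biostrings::writeXStringSet(xs, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read per-sample FASTA/FASTQ reads
#'
#' @param paths named character vector (names = sample ids; defaults to file
#'   base names) of FASTA or FASTQ files.
#' @return named list: sample -> character vector of reads.
#' @export
read_sample_seqs <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.(fasta|fa|fastq|fq)$", "", basename(paths))
  out <- lapply(paths, function(p) {
    fmt <- if (grepl("\\.(fastq|fq)$", p)) "fastq" else "fasta"
    as.character(Biostrings::readDNAStringSet(p, format = fmt))
  })
  lapply(out, unname)
}
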