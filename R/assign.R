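## Gene-labelled taxonomic assignment of OTU representatives against a
## marker database, and per-taxon gyrB/parE paralog ratios.

# percent identity between two sequences under unit-cost global alignment:
# matches / alignment length * 100, with alignment length = max sequence
# length (exact for the substitution-dominated amplicons handled here)
seq_identity <- function(query, subjects) {
  dist <- drop(adist(query, subjects))
  alen <- pmax(nchar(query), nchar(subjects))
  100 * (1 - dist / alen)
}

#' Assign taxonomy and gene labels to OTU representatives
#'
#' Every representative is compared to every database record by global
#' alignment identity; the best hit wins. When several equally good hits
#' disagree, the taxonomy is truncated to their lowest common rank
#' (multi-affiliation); ties across gene labels yield the label
#' `"ambiguous"`. Hits below `min_identity` percent are demoted to phylum
#' rank (deeper ranks unreliable at that divergence).
#'
#' @param otus an `otutab`, or a named character vector of sequences.
#' @param db a `marker_db`.
#' @param min_identity identity (percent) below which taxonomy is truncated
#'   to phylum (default 80).
#' @return `data.frame` with one row per OTU: `otu_id`, `identity`, `gene`,
#'   the seven ranks (NA below the deepest unambiguous rank), `n_hits`,
#'   `hit_ids` (comma-separated marker ids of the best hits).
#' @export
assign_taxonomy <- function(otus, db, min_identity = 80) {
  if (!nrow(db)) stop("empty database", call. = FALSE)
  reps <- if (inherits(otus, "otutab")) otus$representatives else otus
  if (is.null(names(reps))) names(reps) <- paste0("Q", seq_along(reps))
  out <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    ident <- seq_identity(reps[[i]], db$sequence)
    best <- max(ident)
    hits <- which(ident >= best - 1e-9)
    # deterministic in db order: tie-break by marker_id
    hits <- hits[order(db$marker_id[hits])]
    tax <- lca_taxonomy(db[hits, TAX_RANKS, drop = FALSE])
    genes <- unique(db$gene[hits])
    gene <- if (length(genes) == 1L) genes else "ambiguous"
    if (best < min_identity) {
      # keep domain + phylum only
      tax[setdiff(TAX_RANKS, c("domain", "phylum"))] <- NA_character_
    }
    out[[i]] <- data.frame(otu_id = names(reps)[i], identity = best,
                           gene = gene, t(tax), n_hits = length(hits),
                           hit_ids = paste(db$marker_id[hits], collapse = ","),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$gene == "ambiguous"))
    message(sum(res$gene == "ambiguous"),
            " OTU(s) with gene-label ties marked 'ambiguous'")
  res
}

# lowest-common-ancestor truncation across best-hit taxonomies
lca_taxonomy <- function(taxa) {
  out <- setNames(rep(NA_character_, length(TAX_RANKS)), TAX_RANKS)
  for (r in TAX_RANKS) {
    vals <- unique(taxa[[r]])
    if (length(vals) == 1L) out[[r]] <- vals else break
  }
  out
}

#' Per-taxon gyrB fraction across samples (paralog ratios)
#'
#' For each taxon at the requested rank, computes the per-sample fraction of
#' its reads labelled gyrB among gyrB + parE reads, over the samples where
#' the taxon has positive counts, then the mean and SD across those samples.
#'
#' @param assignments output of [assign_taxonomy()].
#' @param otus the matching `otutab`.
#' @param rank taxonomy rank (default `"genus"`).
#' @return `data.frame(taxon, n_samples, mean_gyrb_fraction,
#'   sd_gyrb_fraction)`; single-sample taxa report `sd = 0`. OTUs with
#'   ambiguous gene labels or no taxon at the rank are excluded.
#' @export
paralog_ratios <- function(assignments, otus, rank = "genus") {
  stopifnot(rank %in% TAX_RANKS, inherits(otus, "otutab"))
  a <- assignments[match(rownames(otus$counts), assignments$otu_id), ]
  keep <- a$gene %in% c("gyrB", "parE") & !is.na(a[[rank]])
  counts <- otus$counts[keep, , drop = FALSE]
  a <- a[keep, , drop = FALSE]
  taxa <- sort(unique(a[[rank]]))
  rows <- lapply(taxa, function(tx) {
    sel <- a[[rank]] == tx
    gy <- colSums(counts[sel & a$gene == "gyrB", , drop = FALSE])
    pe <- colSums(counts[sel & a$gene == "parE", , drop = FALSE])
    tot <- gy + pe
    present <- tot > 0
    if (!any(present)) return(NULL)
    frac <- gy[present] / tot[present]
    data.frame(taxon = tx, n_samples = sum(present),
               mean_gyrb_fraction = mean(frac),
               sd_gyrb_fraction = if (sum(present) > 1L) sd(frac) else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
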