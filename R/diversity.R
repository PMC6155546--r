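## Alpha and beta diversity summaries: richness at OTU or merged taxonomic
## rank, analytic rarefaction, median-depth normalization, Bray-Curtis
## distances and principal coordinates.

#' Per-sample richness at OTU or taxonomic rank
#'
#' OTU rank counts OTUs with positive counts; at a taxonomic rank, OTU
#' counts are first merged by their assigned taxon (OTUs unassigned at that
#' rank are pooled as one "unassigned" taxon is *not* done — they are
#' dropped) and nonzero taxa are counted.
#'
#' @param otus an `otutab`.
#' @param rank `"otu"` or one of the seven taxonomy ranks.
#' @param assignments [assign_taxonomy()] output; required for taxonomic
#'   ranks.
#' @return named integer vector, one count per sample.
#' @export
richness <- function(otus, rank = "otu", assignments = NULL) {
  stopifnot(inherits(otus, "otutab"))
  counts <- otus$counts
  if (rank != "otu") {
    stopifnot(rank %in% TAX_RANKS, !is.null(assignments))
    counts <- merge_by_rank(otus, assignments, rank)
  }
  apply(counts > 0, 2L, sum)
}

# merge OTU counts by assigned taxon at a rank (dropping unassigned OTUs)
merge_by_rank <- function(otus, assignments, rank) {
  a <- assignments[match(rownames(otus$counts), assignments$otu_id), ]
  keep <- !is.na(a[[rank]])
  rowsum(otus$counts[keep, , drop = FALSE], a[[rank]][keep])
}

#' Composition table at a taxonomic rank
#'
#' Relative abundances (columns sum to 1) of taxa at the requested rank,
#' merged from assigned OTUs — the plot-ready data behind stacked
#' composition figures.
#'
#' @inheritParams richness
#' @param rank one of the seven taxonomy ranks.
#' @return numeric matrix taxa x samples of fractions.
#' @export
composition_table <- function(otus, assignments, rank = "phylum") {
  m <- merge_by_rank(otus, assignments, rank)
  sweep(m, 2L, pmax(colSums(m), .Machine$double.eps), "/")
}

#' Expected richness in a random subsample (analytic rarefaction)
#'
#' `E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))`, the hypergeometric
#' expectation, evaluated through [vegan::rarefy()] (exact log-gamma
#' arithmetic). Deterministic, unlike repeated subsampling.
#'
#' @param counts integer vector of taxon counts for one sample.
#' @param n subsample size(s), `0 <= n <= sum(counts)`.
#' @return expected richness, one value per `n`.
#' @export
rarefy_expected <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(n < 0 | n > N))
    stop("subsample size must lie in [0, total count]", call. = FALSE)
  vapply(n, function(k) {
    if (k == 0) return(0)
    # vegan warns when tables contain no singletons; irrelevant to the
    # expectation computed here
    suppressWarnings(unname(vegan::rarefy(matrix(counts, nrow = 1L),
                                          sample = k)))
  }, numeric(1L))
}

#' Rarefaction curves for every sample of an OTU table
#'
#' @param otus an `otutab`.
#' @param grid_size number of subsample sizes per sample (spread evenly up
#'   to the sample total).
#' @return `data.frame(sample, n, expected_richness)`.
#' @export
rarefaction_curve <- function(otus, grid_size = 20L) {
  stopifnot(inherits(otus, "otutab"))
  rows <- lapply(colnames(otus$counts), function(s) {
    cnt <- otus$counts[, s]
    N <- sum(cnt)
    grid <- unique(round(seq(0, N, length.out = grid_size + 1L)))
    data.frame(sample = s, n = grid,
               expected_richness = rarefy_expected(cnt, grid),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalize an OTU table to the median sequencing depth
#'
#' Each sample's counts are scaled by (median of sample totals) / (sample
#' total); scaled counts stay fractional (no re-rounding).
#'
#' @param otus an `otutab`.
#' @return the normalized `otutab` (counts possibly fractional).
#' @export
median_depth_normalize <- function(otus) {
  stopifnot(inherits(otus, "otutab"))
  totals <- colSums(otus$counts)
  med <- median(totals)
  factors <- ifelse(totals > 0, med / totals, 0)
  out <- otus
  out$counts <- sweep(otus$counts, 2L, factors, "*")
  out
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(x_i, y_i)) / sum(x_i + y_i)`, accepting fractional
#' abundances; computed via [vegan::vegdist()].
#'
#' @param x,y nonnegative abundance vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Bray-Curtis distance matrix across samples
#'
#' @param otus an `otutab` (samples = columns).
#' @return a `dist` object over samples.
#' @export
bray_curtis_matrix <- function(otus) {
  stopifnot(inherits(otus, "otutab"))
  vegan::vegdist(t(otus$counts), method = "bray")
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centering plus eigendecomposition through [stats::cmdscale()];
#' axes are ordered by eigenvalue and negative eigenvalues (possible for
#' non-Euclidean dissimilarities such as Bray-Curtis) are dropped from the
#' variance denominator with a warning.
#'
#' @param distances a `dist` object or symmetric matrix.
#' @param k number of axes to keep (default: all positive).
#' @return object of class `pcoa_ord`: list with `coordinates` (samples x
#'   axes), `eigenvalues`, `variance_percent` (per kept axis).
#' @export
pcoa_ordination <- function(distances, k = NULL) {
  d <- stats::as.dist(distances)
  n <- attr(d, "Size")
  if (is.null(n) || n < 2L) stop("need at least 2 samples", call. = FALSE)
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # negative/zero eigenvalue handling below reports that itself
  full <- suppressWarnings(cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- full$eig
  if (any(eig < -1e-8))
    warning("negative eigenvalues dropped from the variance denominator ",
            "(non-Euclidean dissimilarity)", call. = FALSE)
  pos <- eig > 1e-8
  denom <- sum(eig[pos])
  npos <- sum(pos)
  if (is.null(k)) k <- npos else k <- min(k, npos)
  coords <- full$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 variance_percent = 100 * eig[seq_len(k)] / denom),
            class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("pcoa_ord: %d samples, %d axes (%s%% variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f", x$variance_percent), collapse = "/")))
  invisible(x)
}
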