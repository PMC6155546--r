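## Read processing: dereplication, swarm-style single-linkage clustering at a
## fixed edit distance, de-novo chimera removal and low-abundance filtering.

#' Dereplicate reads into unique sequences with per-sample counts
#'
#' @param reads named list: sample -> character vector of reads.
#' @return object of class `derep`: list with `seqs` (unique sequences,
#'   ordered by total count descending then lexicographically) and `counts`
#'   (integer matrix, uniques x samples).
#' @export
dereplicate <- function(reads) {
  stopifnot(is.list(reads))
  samples <- names(reads)
  if (is.null(samples)) samples <- paste0("S", seq_along(reads))
  all_seqs <- unlist(reads, use.names = FALSE)
  u <- unique(all_seqs)
  counts <- vapply(reads, function(r) tabulate(match(r, u), length(u)),
                   integer(length(u)))
  counts <- matrix(counts, nrow = length(u), ncol = length(samples),
                   dimnames = list(NULL, samples))
  ord <- order(-rowSums(counts), u)
  structure(list(seqs = u[ord],
                 counts = counts[ord, , drop = FALSE]),
            class = "derep")
}

#' @export
print.derep <- function(x, ...) {
  cat(sprintf("derep: %d unique sequences over %d reads, %d sample(s)\n",
              length(x$seqs), sum(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Swarm-style clustering: single-linkage components at edit distance d
#'
#' OTUs are the connected components of the graph joining unique sequences at
#' Levenshtein distance <= `d` (transitive agglomeration, the swarm
#' semantics). The representative is the highest-count member, ties broken
#' lexicographically; OTU ids are assigned in decreasing total-count order
#' (`Cluster_1` most abundant).
#'
#' @param derep a [dereplicate()] object.
#' @param d clustering distance (default 3).
#' @return object of class `otutab`: list with `counts` (OTU x sample integer
#'   matrix), `representatives` (named character), `members` (list of member
#'   sequences) and `d`.
#' @export
swarm_cluster <- function(derep, d = 3L) {
  stopifnot(inherits(derep, "derep"), d >= 0)
  seqs <- derep$seqs
  if (!length(seqs))
    return(build_otutab(seqs, derep$counts, integer(0), d))
  comp <- cpp_swarm_components(seqs, as.integer(d))
  build_otutab(seqs, derep$counts, comp, d)
}

# assemble an otutab from a component labelling of the dereplicated uniques
build_otutab <- function(seqs, counts, comp, d) {
  if (!length(seqs)) {
    empty <- matrix(integer(0), nrow = 0, ncol = ncol(counts),
                    dimnames = list(NULL, colnames(counts)))
    return(structure(list(counts = empty, representatives = character(0),
                          members = list(), d = d), class = "otutab"))
  }
  ncomp <- max(comp)
  totals <- rowSums(counts)
  otu_counts <- rowsum(counts, comp)          # component x sample
  members <- split(seqs, comp)
  reps <- vapply(seq_len(ncomp), function(k) {
    idx <- which(comp == k)
    idx <- idx[order(-totals[idx], seqs[idx])]
    seqs[idx[1L]]
  }, character(1L))
  ord <- order(-rowSums(otu_counts), reps)
  otu_counts <- otu_counts[ord, , drop = FALSE]
  reps <- reps[ord]
  members <- members[as.character(ord)]
  ids <- paste0("Cluster_", seq_len(ncomp))
  rownames(otu_counts) <- ids
  names(reps) <- ids
  names(members) <- ids
  structure(list(counts = otu_counts, representatives = reps,
                 members = members, d = d),
            class = "otutab")
}

#' @export
print.otutab <- function(x, ...) {
  cat(sprintf("otutab: %d OTUs x %d sample(s), %s reads (d = %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ","), x$d))
  inv <- c(chimera = attr(x, "chimera_removed_reads"),
           filter = attr(x, "filter_removed_reads"))
  if (length(inv))
    cat("  removed reads:", paste(names(inv), inv, collapse = ", "), "\n")
  invisible(x)
}

# Shared two-parent decomposition test: does `query` split at some breakpoint
# into an exact prefix of one parent and an exact suffix of another (distinct)
# parent, without being within d edits of any single parent?
is_two_parent_chimera <- function(query, parent_seqs, d, exempt_near = TRUE) {
  if (length(parent_seqs) < 2L) return(FALSE)
  L <- nchar(query)
  lcp <- cpp_lcp(query, parent_seqs)
  lcs <- cpp_lcs(query, parent_seqs)
  best <- -Inf
  top_lcp <- order(-lcp)[1L]
  second_lcp <- order(-lcp)[2L]
  for (b in seq_along(parent_seqs)) {
    if (lcs[b] < 1L) next
    a <- if (b == top_lcp) second_lcp else top_lcp
    if (is.na(a) || lcp[a] < 1L) next
    best <- max(best, lcp[a] + lcs[b])
  }
  if (!is.finite(best) || best < L) return(FALSE)
  if (!exempt_near) return(TRUE)
  !any(cpp_match_any(query, parent_seqs, as.integer(d)))
}

#' Remove chimeric unique sequences before clustering
#'
#' De-novo chimera filtering applied to the abundance-sorted dereplicated
#' sequences: a unique sequence is dropped when it decomposes at some
#' breakpoint into a prefix of one sufficiently abundant unique and a suffix
#' of another (distinct) one, allowing up to `d` residual substitutions
#' (sequencing errors on the chimera), provided the decomposition beats the
#' best single-parent match. Removing chimeras *before* single-linkage
#' clustering is essential: a series of chimeras of the same two
#' near-identical parents with staggered breakpoints otherwise forms a
#' stepping-stone path that chains the parents' clusters together.
#' Candidate parents are capped at the `max_parents` most abundant uniques.
#'
#' @param derep a [dereplicate()] object.
#' @param skew minimum parent/query abundance ratio (default 2).
#' @param d residual substitution allowance (defaults to the clustering
#'   distance).
#' @param margin a decomposition must beat the best single-parent match by
#'   at least this many mismatches (default 2; protects reads whose terminal
#'   sequencing error coincides with another reference).
#' @param max_parents parent pool size (default 64).
#' @return the filtered `derep`, with attributes `chimera_removed_reads` and
#'   `chimera_removed_seqs`.
#' @export
prefilter_chimeras <- function(derep, skew = 2, d = 3L, margin = 2L,
                               max_parents = 64L) {
  stopifnot(inherits(derep, "derep"))
  totals <- rowSums(derep$counts)
  seqs <- derep$seqs
  n <- length(seqs)
  top <- seq_len(min(max_parents, n))
  flagged <- logical(n)
  for (i in seq_len(n)) {
    parents <- top[totals[top] >= skew * totals[i]]
    parents <- setdiff(parents, i)
    if (length(parents) < 2L) next
    sc <- cpp_chimera_score(seqs[i], seqs[parents])
    if (sc[1L] < .Machine$integer.max / 4) {
      # equal-length parents: approximate decomposition, must strictly beat
      # the best single parent
      flagged[i] <- sc[1L] <= d && sc[1L] + margin <= sc[2L]
    } else {
      # unequal lengths: exact decomposition only
      flagged[i] <- is_two_parent_chimera(seqs[i], seqs[parents], d,
                                          exempt_near = FALSE)
    }
  }
  if (any(flagged))
    message(sum(flagged), " chimeric unique sequence(s) removed before ",
            "clustering (", sum(totals[flagged]), " reads)")
  out <- structure(list(seqs = seqs[!flagged],
                        counts = derep$counts[!flagged, , drop = FALSE]),
                   class = "derep")
  attr(out, "chimera_removed_reads") <- sum(totals[flagged])
  attr(out, "chimera_removed_seqs") <- seqs[flagged]
  out
}

#' De-novo removal of two-parent chimeric OTUs
#'
#' An OTU is flagged chimeric when its representative splits at some
#' breakpoint into a prefix exactly matching one parent representative and a
#' suffix exactly matching another, with both parents at least `skew` times
#' as abundant, and the OTU is not within `d` edits of any single parent.
#' This is a deliberate simplification of de-novo chimera detection (exact
#' two-parent crossover, fixed abundance skew); it can be switched off by
#' passing `skew = Inf`.
#'
#' @param otus an `otutab`.
#' @param skew minimum parent/query abundance ratio (default 2).
#' @param d distance used for the single-parent proximity check (defaults to
#'   the table's clustering distance).
#' @return the filtered `otutab`, with attributes `chimera_removed_reads`
#'   and `chimera_removed_ids` recording what was dropped.
#' @export
remove_chimeras <- function(otus, skew = 2, d = otus$d) {
  stopifnot(inherits(otus, "otutab"))
  totals <- rowSums(otus$counts)
  reps <- otus$representatives
  n <- length(reps)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    parents <- which(totals >= skew * totals[i])
    parents <- setdiff(parents, i)
    if (length(parents) < 2L) next
    flagged[i] <- is_two_parent_chimera(reps[i], reps[parents], d)
  }
  if (any(flagged))
    message(sum(flagged), " chimeric OTU(s) removed (",
            sum(totals[flagged]), " reads)")
  out <- subset_otutab(otus, !flagged)
  attr(out, "chimera_removed_reads") <- sum(totals[flagged])
  attr(out, "chimera_removed_ids") <- names(reps)[flagged]
  out
}

subset_otutab <- function(otus, keep) {
  structure(list(counts = otus$counts[keep, , drop = FALSE],
                 representatives = otus$representatives[keep],
                 members = otus$members[keep], d = otus$d),
            class = "otutab")
}

#' Drop OTUs below a whole-dataset abundance threshold
#'
#' Retains OTUs whose total count across all samples is at least `min_total`
#' (the default 11 implements the "more than 10 times in the whole dataset"
#' rule); the removed counts are logged in attributes.
#'
#' @param otus an `otutab`.
#' @param min_total minimum whole-dataset total (default 11).
#' @return filtered `otutab` with attributes `filter_removed_reads` and
#'   `filter_removed_ids` (carries over chimera-removal attributes).
#' @export
abundance_filter <- function(otus, min_total = 11L) {
  stopifnot(inherits(otus, "otutab"))
  totals <- rowSums(otus$counts)
  keep <- totals >= min_total
  if (!any(keep))
    warning("all OTUs fall below the abundance threshold", call. = FALSE)
  out <- subset_otutab(otus, keep)
  attr(out, "chimera_removed_reads") <- attr(otus, "chimera_removed_reads")
  attr(out, "chimera_removed_ids") <- attr(otus, "chimera_removed_ids")
  attr(out, "filter_removed_reads") <- sum(totals[!keep])
  attr(out, "filter_removed_ids") <- names(otus$representatives)[!keep]
  out
}

#' Reads-to-OTU-table convenience chain
#'
#' Dereplicates, removes chimeric uniques ([prefilter_chimeras()]), clusters
#' ([swarm_cluster()]), removes chimeric OTUs ([remove_chimeras()]) and
#' applies the abundance filter — the canonical processing chain. The
#' returned table's attributes account for every input read
#' (`sum(counts) + chimera_removed_reads + filter_removed_reads` equals the
#' read input).
#'
#' @param reads named list: sample -> character vector of reads.
#' @param d clustering distance (default 3).
#' @param min_total whole-dataset abundance threshold (default 11).
#' @param chimeras `"both"` (default), `"pre"`, `"otu"` or `"none"`.
#' @param skew chimera parent/query abundance ratio.
#' @return a filtered `otutab`.
#' @export
cluster_reads <- function(reads, d = 3L, min_total = 11L,
                          chimeras = c("both", "pre", "otu", "none"),
                          skew = 2) {
  chimeras <- match.arg(chimeras)
  derep <- dereplicate(reads)
  pre_removed <- 0
  if (chimeras %in% c("both", "pre")) {
    derep <- prefilter_chimeras(derep, skew = skew, d = d)
    pre_removed <- attr(derep, "chimera_removed_reads")
  }
  otus <- swarm_cluster(derep, d = d)
  if (chimeras %in% c("both", "otu")) otus <- remove_chimeras(otus, skew = skew)
  out <- abundance_filter(otus, min_total = min_total)
  attr(out, "chimera_removed_reads") <-
    pre_removed + (attr(out, "chimera_removed_reads") %||% 0)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write an OTU table (and representatives) to disk
#'
#' @param otus an `otutab`.
#' @param tsv output TSV path (rows = OTUs, columns = samples; first columns
#'   are `otu_id` and `representative`).
#' @param rep_fasta optional FASTA path for representative sequences.
#' @param seed optional seed recorded as a header comment.
#' @return `tsv`, invisibly.
#' @export
write_otutab <- function(otus, tsv, rep_fasta = NULL, seed = NULL) {
  df <- data.frame(otu_id = rownames(otus$counts),
                   representative = unname(otus$representatives),
                   otus$counts, check.names = FALSE)
  con <- file(tsv, "w")
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(rep_fasta)) {
    xs <- Biostrings::DNAStringSet(otus$representatives)
    Biostrings::writeXStringSet(xs, rep_fasta)
  }
  invisible(tsv)
}
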