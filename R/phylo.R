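## Kimura 2-parameter distances and neighbor-joining trees over marker
## amplicons and OTU representatives.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' With transition fraction `P` and transversion fraction `Q` over the
#' compared sites, `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` substitutions
#' per site. Sites where either sequence carries a non-ACGT character are
#' excluded (pairwise deletion); unequal-length inputs are compared over
#' their common prefix (the amplicons handled here are coordinate-homologous
#' by construction).
#'
#' @param a,b nucleotide strings.
#' @return distance in substitutions/site.
#' @examples
#' k2p_distance("AAAA", "AAAA")  # 0
#' @export
k2p_distance <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) stop("empty sequence", call. = FALSE)
  ca <- strsplit(toupper(substr(a, 1L, n)), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(substr(b, 1L, n)), "", fixed = TRUE)[[1L]]
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  ca <- ca[ok]; cb <- cb[ok]
  m <- length(ca)
  if (m == 0L) stop("no comparable sites after pairwise deletion", call. = FALSE)
  diff <- ca != cb
  ts <- sum(diff & ((ca %in% PURINES & cb %in% PURINES) |
                    (ca %in% PYRIMIDINES & cb %in% PYRIMIDINES)))
  tv <- sum(diff) - ts
  P <- ts / m
  Q <- tv / m
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance saturated (1-2P-Q or 1-2Q <= 0)", call. = FALSE)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise distance matrix under K2P or p-distance
#'
#' @param seqs character vector of sequences.
#' @param labels row/column labels (default names of `seqs`).
#' @param model `"K2P"` or `"p"` (proportion of differing sites).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs, labels = names(seqs),
                            model = c("K2P", "p")) {
  model <- match.arg(model)
  n <- length(seqs)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      m[i, j] <- m[j, i] <- if (model == "K2P") k2p_distance(seqs[i], seqs[j])
                            else p_distance(seqs[i], seqs[j])
    }
  }
  m
}

p_distance <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  ca <- strsplit(toupper(substr(a, 1L, n)), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(substr(b, 1L, n)), "", fixed = TRUE)[[1L]]
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  if (!any(ok)) stop("no comparable sites after pairwise deletion", call. = FALSE)
  mean(ca[ok] != cb[ok])
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]); on additive
#' distances the generating topology is reconstructed exactly and path
#' lengths match the input. Negative branch lengths (possible on
#' non-additive input) are clamped to zero with the deficit moved to the
#' sibling edge, with a message.
#'
#' @param dm symmetric distance matrix (>= 3 labels) or `dist`.
#' @return an [ape] `phylo` tree (unrooted).
#' @export
neighbor_joining <- function(dm) {
  m <- as.matrix(dm)
  if (nrow(m) < 3L) stop("need at least 3 labels", call. = FALSE)
  tree <- ape::nj(as.dist(m))
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    message(length(neg), " negative NJ branch length(s) clamped to 0")
    for (e in neg) {
      deficit <- tree$edge.length[e]
      parent <- tree$edge[e, 1L]
      sib <- setdiff(which(tree$edge[, 1L] == parent), e)
      if (length(sib)) {
        s <- sib[1L]
        tree$edge.length[s] <- max(0, tree$edge.length[s] + deficit)
      }
      tree$edge.length[e] <- 0
    }
  }
  tree
}

#' Build a neighbor-joining marker tree from a database or representatives
#'
#' Computes the K2P matrix over the (coordinate-homologous) amplicons and
#' runs neighbor joining; leaves are labelled `marker_id|gene|species` for a
#' `marker_db`, or by element names otherwise.
#'
#' @param x a `marker_db`, or a named character vector of sequences.
#' @param newick optional path: serialize the tree as newick.
#' @return an [ape] `phylo` tree.
#' @export
build_marker_tree <- function(x, newick = NULL) {
  if (inherits(x, "marker_db")) {
    seqs <- x$sequence
    labels <- paste(x$marker_id, x$gene, x$species, sep = "|")
  } else {
    seqs <- as.character(x)
    labels <- names(x)
    if (is.null(labels)) labels <- paste0("seq", seq_along(seqs))
  }
  if (length(seqs) < 3L) stop("need at least 3 sequences", call. = FALSE)
  dm <- distance_matrix(seqs, labels, model = "K2P")
  tree <- neighbor_joining(dm)
  if (!is.null(newick)) ape::write.tree(tree, newick)
  tree
}
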