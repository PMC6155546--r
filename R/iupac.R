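## IUPAC-aware degenerate-primer matching.
##
## Each IUPAC code is a bitmask over {A=1, C=2, G=4, T=8}; a primer position
## matches a template base when the intersection of their sets is non-empty.

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  M = 3L,  # A/C
  R = 5L,  # A/G
  W = 9L,  # A/T
  S = 6L,  # C/G
  Y = 10L, # C/T
  K = 12L, # G/T
  V = 7L,  # A/C/G
  H = 11L, # A/C/T
  D = 13L, # A/G/T
  B = 14L, # C/G/T
  N = 15L
)

# One deterministic concrete base per code (used when a degenerate primer has
# to be written out as plain DNA, e.g. for synthetic genome records).
IUPAC_CONCRETE <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  M = "A", R = "A", W = "A", S = "C", Y = "C", K = "G",
  V = "A", H = "A", D = "A", B = "C", N = "A"
)

seq_to_mask <- function(x, what = "sequence") {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  m <- IUPAC_BITS[chars]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop(sprintf("invalid IUPAC code '%s' at position %d of %s",
                 chars[bad], bad, what), call. = FALSE)
  }
  unname(m)
}

#' Reverse complement of a (possibly degenerate) nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that works on plain
#' character vectors and handles all IUPAC ambiguity codes.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Count mismatches of a degenerate primer against an equal-length window
#'
#' A position matches when the window base belongs to the primer code's base
#' set (e.g. `R` matches `A` or `G`, `N` matches anything).
#'
#' @param primer IUPAC primer string.
#' @param window nucleotide window of the same length.
#' @param max_mismatches non-negative mismatch budget.
#' @return integer mismatch count, or `NA_integer_` when the count exceeds
#'   `max_mismatches` (no match).
#' @examples
#' iupac_match("ACGGRAGGCWGCAGT", "ACGGAAGGCAGCAGT", 0)  # 0
#' iupac_match("AAAA", "AAAT", 0)                        # NA: over budget
#' @export
iupac_match <- function(primer, window, max_mismatches = 0L) {
  pm <- seq_to_mask(primer, "primer")
  wm <- seq_to_mask(window, "window")
  if (length(pm) != length(wm))
    stop("primer and window must have equal lengths", call. = FALSE)
  mism <- sum(bitwAnd(pm, wm) == 0L)
  if (mism > max_mismatches) NA_integer_ else as.integer(mism)
}

#' Construct a degenerate primer pair
#'
#' @param forward,reverse primer strings 5'->3' as synthesized (the reverse
#'   primer anneals to the plus strand as its reverse complement).
#' @param max_mismatches mismatch budget per primer site.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, max_mismatches = 0L) {
  seq_to_mask(forward, "forward primer")
  seq_to_mask(reverse, "reverse primer")
  stopifnot(max_mismatches >= 0)
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 max_mismatches = as.integer(max_mismatches)),
            class = "primer_pair")
}

#' Built-in primer presets
#'
#' `"gyrB"` is the degenerate F64/R353 pair targeting a ~280-bp region of the
#' gyrB gene (which also anneals to the parE paralog in Firmicutes); `"V3V4"`
#' targets the 16S rRNA V3-V4 region.
#'
#' @param name `"gyrB"` or `"V3V4"`.
#' @param max_mismatches mismatch budget per primer site.
#' @return a [primer_pair()].
#' @export
primer_preset <- function(name = c("gyrB", "V3V4"), max_mismatches = 0L) {
  name <- match.arg(name)
  switch(name,
    gyrB = primer_pair("MGNCCNGSNATGTAYATHGG", "CNCCRTGNARDCCDCCNGA",
                       max_mismatches),
    V3V4 = primer_pair("ACGGRAGGCWGCAGT", "TACCAGGGTATCTAATCCT",
                       max_mismatches)
  )
}

# Resolve a degenerate string to one concrete DNA realization.
concretize_primer <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  paste(IUPAC_CONCRETE[chars], collapse = "")
}

# All primer site positions on a template (plus strand), with mismatch
# counts. Returns a data.frame(start, mismatches), starts ascending.
scan_primer <- function(template_mask, primer_mask, max_mismatches) {
  n <- length(template_mask)
  m <- length(primer_mask)
  if (n < m) return(data.frame(start = integer(), mismatches = integer()))
  starts <- integer()
  mms <- integer()
  for (i in seq_len(n - m + 1L)) {
    mm <- sum(bitwAnd(primer_mask, template_mask[i:(i + m - 1L)]) == 0L)
    if (mm <= max_mismatches) {
      starts <- c(starts, i)
      mms <- c(mms, mm)
    }
  }
  data.frame(start = starts, mismatches = mms)
}
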