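#' In-silico PCR: extract the amplicon insert between two primer sites
#'
#' Locates the forward primer on the template and the reverse primer as its
#' reverse complement downstream, and returns the insert *between* the two
#' sites (primers excluded, mirroring adapter trimming). When several site
#' pairs exist, the leftmost forward site with its nearest valid reverse site
#' wins. Both strands are searched; the insert is always reported in the
#' canonical forward-primer orientation, with `strand` recording which
#' template strand carried the sites.
#'
#' @param template nucleotide string.
#' @param primers a [primer_pair()].
#' @param both_strands search the reverse complement too (default `TRUE`).
#' @return `NULL` when no site pair exists; otherwise a list with elements
#'   `insert` (canonical orientation), `strand` (`"+"`/`"-"`), `fwd` and
#'   `rev` (each a list `start`, `end` (exclusive), `mismatches`, 0-based on
#'   the searched strand).
#' @examples
#' pp <- primer_pair("ACGTACGT", "TTTTCCCC")
#' tpl <- paste0("ACGTACGT", strrep("A", 20), revcomp("TTTTCCCC"))
#' amplify(tpl, pp)$insert  # 20 x A
#' @export
amplify <- function(template, primers, both_strands = TRUE) {
  stopifnot(inherits(primers, "primer_pair"))
  fwd_mask <- seq_to_mask(primers$forward, "forward primer")
  # reverse primer anneals as its reverse complement on the searched strand
  rev_site <- revcomp(primers$reverse)
  rev_mask <- seq_to_mask(rev_site, "reverse primer")
  hit <- amplify_one_strand(template, fwd_mask, rev_mask,
                            primers$max_mismatches)
  if (!is.null(hit)) {
    hit$strand <- "+"
    return(hit)
  }
  if (both_strands) {
    hit <- amplify_one_strand(revcomp(template), fwd_mask, rev_mask,
                              primers$max_mismatches)
    if (!is.null(hit)) {
      hit$strand <- "-"
      return(hit)
    }
  }
  NULL
}

amplify_one_strand <- function(template, fwd_mask, rev_mask, max_mm) {
  tm <- seq_to_mask(template, "template")
  f_hits <- scan_primer(tm, fwd_mask, max_mm)
  if (nrow(f_hits) == 0L) return(NULL)
  r_hits <- scan_primer(tm, rev_mask, max_mm)
  if (nrow(r_hits) == 0L) return(NULL)
  flen <- length(fwd_mask)
  rlen <- length(rev_mask)
  # leftmost forward that still has a valid (non-overlapping) reverse site
  for (k in seq_len(nrow(f_hits))) {
    f_start <- f_hits$start[k]
    f_end <- f_start + flen  # 1-based exclusive
    ok <- r_hits$start >= f_end
    if (any(ok)) {
      r_start <- min(r_hits$start[ok])
      r_mm <- r_hits$mismatches[ok][which.min(r_hits$start[ok])]
      insert <- if (r_start > f_end) substr(template, f_end, r_start - 1L)
                else ""
      return(list(
        insert = insert,
        fwd = list(start = f_start - 1L, end = f_end - 1L,
                   mismatches = f_hits$mismatches[k]),
        rev = list(start = r_start - 1L, end = r_start + rlen - 1L,
                   mismatches = r_mm)
      ))
    }
  }
  NULL
}
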