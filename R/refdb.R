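## Paralog-aware marker reference database construction.
##
## A genome record is a list(record_id, taxonomy, genes) where taxonomy is a
## named character vector over the seven canonical ranks (plus an optional
## "strain") and genes is a data.frame(gene, sequence). Marker databases are
## data.frames (class "marker_db") with one primer-trimmed amplicon per row.

#' Construct a genome record
#'
#' @param record_id identifier.
#' @param taxonomy either a `domain;phylum;class;order;family;genus;species`
#'   (optionally `;strain`) string or a named character vector.
#' @param genes `data.frame` with columns `gene` and `sequence`.
#' @return object of class `genome_record`.
#' @export
genome_record <- function(record_id, taxonomy, genes) {
  tax <- parse_taxonomy(taxonomy)
  if (!is.data.frame(genes) || !all(c("gene", "sequence") %in% names(genes)))
    stop(sprintf("malformed genome record '%s': genes must be a data.frame with columns gene, sequence",
                 record_id), call. = FALSE)
  for (i in seq_len(nrow(genes))) {
    ok <- grepl("^[ACGTUMRWSYKVHDBNacgtumrwsykvhdbn]*$", genes$sequence[i])
    if (!ok || !nzchar(genes$sequence[i]))
      stop(sprintf("malformed genome record '%s': gene '%s' has an invalid sequence",
                   record_id, genes$gene[i]), call. = FALSE)
  }
  structure(list(record_id = as.character(record_id), taxonomy = tax,
                 genes = genes[, c("gene", "sequence")]),
            class = "genome_record")
}

parse_taxonomy <- function(taxonomy) {
  if (is.character(taxonomy) && length(taxonomy) == 1L && is.null(names(taxonomy))) {
    parts <- strsplit(taxonomy, ";", fixed = TRUE)[[1L]]
    parts <- trimws(parts)
    if (length(parts) < 7L || length(parts) > 8L)
      stop("taxonomy must have 7 ranks (domain..species), optionally + strain",
           call. = FALSE)
    names(parts) <- c(TAX_RANKS, "strain")[seq_along(parts)]
    if (length(parts) == 7L) parts <- c(parts, strain = "")
    return(parts)
  }
  if (!all(TAX_RANKS %in% names(taxonomy)))
    stop("taxonomy must be named over ranks domain..species", call. = FALSE)
  out <- taxonomy[TAX_RANKS]
  c(out, strain = if ("strain" %in% names(taxonomy)) unname(taxonomy[["strain"]]) else "")
}

#' Read genome records from a gene table TSV
#'
#' The table must have columns `taxonomy`, `gene`, `sequence` and optionally
#' `record_id`; rows sharing a `record_id` (or, failing that, a taxonomy
#' string) form one record.
#'
#' @param path TSV path.
#' @return list of [genome_record()] objects.
#' @export
read_genome_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("taxonomy", "gene", "sequence")
  if (!all(need %in% names(df)))
    stop("gene table must have columns taxonomy, gene, sequence", call. = FALSE)
  key <- if ("record_id" %in% names(df)) df$record_id else df$taxonomy
  idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(names(idx), function(k) {
    rows <- idx[[k]]
    genome_record(record_id = k, taxonomy = df$taxonomy[rows[1L]],
                  genes = df[rows, c("gene", "sequence")])
  })
}

#' Read genome records from GFF3 annotation plus a FASTA
#'
#' Standard-format input path: gene features are taken from the GFF3 (via
#' rtracklayer), sequences from the FASTA, and the taxonomy from a
#' per-sequence `taxonomy` entry in `taxa` keyed by seqnames.
#'
#' @param gff,fasta file paths.
#' @param taxa named character vector: seqname -> taxonomy string.
#' @return list of [genome_record()] objects.
#' @export
read_genome_gff <- function(gff, fasta, taxa) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("the GFF3 input path requires the rtracklayer package", call. = FALSE)
  gr <- rtracklayer::import(gff)
  gr <- gr[gr$type %in% c("gene", "CDS")]
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- list()
  for (sn in unique(as.character(GenomicRanges::seqnames(gr)))) {
    if (!sn %in% names(taxa))
      stop(sprintf("no taxonomy supplied for sequence '%s'", sn), call. = FALSE)
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == sn]
    gene_names <- if (!is.null(sub$gene)) sub$gene else sub$Name
    keep <- !is.na(gene_names)
    sub <- sub[keep]
    gene_names <- gene_names[keep]
    gseq <- vapply(seq_along(sub), function(i) {
      s <- Biostrings::subseq(seqs[[sn]], GenomicRanges::start(sub[i]),
                              GenomicRanges::end(sub[i]))
      if (as.character(GenomicRanges::strand(sub[i])) == "-")
        s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1L))
    out[[length(out) + 1L]] <- genome_record(
      record_id = sn, taxonomy = taxa[[sn]],
      genes = data.frame(gene = gene_names, sequence = gseq))
  }
  out
}

#' Extract annotated genes matching requested names
#'
#' Case-insensitive exact match on the gene name; synonyms can be added to
#' `gene_names` directly.
#'
#' @param record a [genome_record()].
#' @param gene_names character vector of names to keep (e.g.
#'   `c("gyrB", "parE")`).
#' @return `data.frame(gene, sequence)` with the annotated label preserved;
#'   zero rows when nothing matches.
#' @export
extract_marker_genes <- function(record, gene_names) {
  if (!inherits(record, "genome_record"))
    stop("record must be a genome_record", call. = FALSE)
  if (length(gene_names) == 0L) stop("gene_names must be nonempty", call. = FALSE)
  hit <- tolower(record$genes$gene) %in% tolower(gene_names)
  record$genes[hit, , drop = FALSE]
}

#' Build a paralog-aware marker database by in-silico PCR
#'
#' Extracts the requested genes from every record, keeps only those bracketed
#' by both degenerate primers ([amplify()]), stores the primer-trimmed insert
#' and collapses exact duplicates on (sequence, species, gene).
#'
#' @param records list of [genome_record()] objects.
#' @param primers a [primer_pair()] (default: the gyrB preset).
#' @param gene_names genes to extract.
#' @param dedup collapse duplicate (sequence, species, gene) triples
#'   (default `TRUE`).
#' @return a `marker_db` data.frame with columns `marker_id`, `gene`,
#'   the seven ranks, `strain` and `sequence`.
#' @export
build_database <- function(records, primers = primer_preset("gyrB"),
                           gene_names = c("gyrB", "parE"), dedup = TRUE) {
  rows <- list()
  for (rec in records) {
    genes <- extract_marker_genes(rec, gene_names)
    for (i in seq_len(nrow(genes))) {
      amp <- amplify(genes$sequence[i], primers)
      if (is.null(amp) || !nzchar(amp$insert)) next  # primer(s) absent: discard
      tax <- rec$taxonomy
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = paste0(rec$record_id, "_", genes$gene[i]),
        gene = genes$gene[i],
        t(tax[c(TAX_RANKS, "strain")]),
        sequence = amp$insert,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    stop("empty database: no gene contained both primer sites", call. = FALSE)
  db <- do.call(rbind, rows)
  if (dedup) {
    key <- paste(db$sequence, db$species, db$gene, sep = "\r")
    db <- db[!duplicated(key), , drop = FALSE]
  }
  # disambiguate marker ids if a record contributed several copies of a gene
  db$marker_id <- make.unique(db$marker_id, sep = "_")
  rownames(db) <- NULL
  class(db) <- c("marker_db", "data.frame")
  db
}

marker_header <- function(db) {
  tax <- apply(db[, c(TAX_RANKS, "strain")], 1L, paste, collapse = ";")
  paste(db$marker_id, db$gene, tax, sep = "|")
}

#' Write a marker database as FASTA (with sidecar TSV)
#'
#' Headers follow `marker_id|gene|domain;...;species;strain`.
#'
#' @param db a `marker_db`.
#' @param fasta output FASTA path.
#' @param tsv optional sidecar TSV path.
#' @return `fasta`, invisibly.
#' @export
write_marker_fasta <- function(db, fasta, tsv = NULL) {
  xs <- Biostrings::DNAStringSet(db$sequence)
  names(xs) <- marker_header(db)
  Biostrings::writeXStringSet(xs, fasta)
  if (!is.null(tsv))
    write.table(db, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta)
}

#' Read a marker database back from FASTA
#'
#' @param fasta FASTA written by [write_marker_fasta()].
#' @return a `marker_db` data.frame.
#' @export
read_marker_fasta <- function(fasta) {
  xs <- Biostrings::readDNAStringSet(fasta)
  parts <- strsplit(names(xs), "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed marker FASTA header: ", names(xs)[bad][1L], call. = FALSE)
  tax <- t(vapply(parts, function(p) {
    tp <- strsplit(p[3L], ";", fixed = TRUE)[[1L]]
    length(tp) <- 8L
    tp[is.na(tp)] <- ""
    tp
  }, character(8L)))
  colnames(tax) <- c(TAX_RANKS, "strain")
  db <- data.frame(
    marker_id = vapply(parts, `[`, character(1L), 1L),
    gene = vapply(parts, `[`, character(1L), 2L),
    tax, sequence = as.character(xs), stringsAsFactors = FALSE)
  rownames(db) <- NULL
  class(db) <- c("marker_db", "data.frame")
  db
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf("marker_db: %d sequences (%s), %d species\n",
              nrow(x), paste(sprintf("%s: %d", names(table(x$gene)),
                                     as.integer(table(x$gene))),
                             collapse = ", "),
              length(unique(x$species))))
  invisible(x)
}
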