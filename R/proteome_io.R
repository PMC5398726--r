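#' Header-parsing rule for proteome FASTA files
#'
#' Builds a function that maps FASTA header lines to protein and gene
#' identifiers. The default rule takes the first whitespace-delimited token of
#' the header as the protein id and derives the gene id by stripping a trailing
#' isoform suffix such as \code{.t2} or \code{.p1} — the common convention in
#' nematode gene models (\code{g123.t1} is an isoform of gene \code{g123}).
#'
#' @param isoform_pattern Regular expression removed from the protein id to
#'   obtain the gene id. Set to \code{NULL} to use the protein id itself as the
#'   gene id (one isoform per gene).
#' @return A function taking a character vector of headers and returning a
#'   data.frame with columns \code{protein_id} and \code{gene_id}.
#' @examples
#' p <- fasta_id_parser()
#' p(c("g1.t1 some description", "g1.t2"))
#' @export
fasta_id_parser <- function(isoform_pattern = "\\.[tp][0-9]+$") {
  force(isoform_pattern)
  function(headers) {
    protein_id <- sub("\\s.*$", "", headers)
    gene_id <- if (is.null(isoform_pattern)) protein_id else
      sub(isoform_pattern, "", protein_id)
    data.frame(protein_id = protein_id, gene_id = gene_id,
               stringsAsFactors = FALSE)
  }
}

new_proteome <- function(species_id, records, isoform_filtered = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "gene_id", "sequence") %in% names(records)))
  structure(list(species_id = species_id,
                 records = records,
                 isoform_filtered = isoform_filtered),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome> species '%s': %d proteins, %d genes%s\n",
              x$species_id, nrow(x$records),
              length(unique(x$records$gene_id)),
              if (x$isoform_filtered) " (longest-isoform filtered)" else ""))
  invisible(x)
}

validate_proteome_records <- function(records) {
  if (any(!nzchar(records$sequence)))
    stop("empty sequence for protein(s): ",
         paste(records$protein_id[!nzchar(records$sequence)], collapse = ", "))
  dup <- records$protein_id[duplicated(records$protein_id)]
  if (length(dup))
    stop("duplicate protein_id within species: ",
         paste(unique(dup), collapse = ", "))
  if (any(!nzchar(records$gene_id)))
    stop("empty gene_id for protein(s): ",
         paste(records$protein_id[!nzchar(records$gene_id)], collapse = ", "))
  invisible(records)
}

#' Read a proteome FASTA file
#'
#' Reads amino-acid FASTA (multi-line sequences supported), parses headers into
#' protein and gene ids, and returns a \code{proteome} object. Sequences are
#' uppercased; entry order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param species_id Species label attached to every record.
#' @param id_parser Header rule, see [fasta_id_parser()].
#' @return A \code{proteome}: list with \code{species_id}, a \code{records}
#'   data.frame (\code{protein_id}, \code{gene_id}, \code{sequence}) and the
#'   \code{isoform_filtered} flag.
#' @seealso [write_proteome_fasta()], [longest_isoform_filter()]
#' @export
read_proteome_fasta <- function(path, species_id,
                                id_parser = fasta_id_parser()) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    return(new_proteome(species_id,
                        data.frame(protein_id = character(),
                                   gene_id = character(),
                                   sequence = character(),
                                   stringsAsFactors = FALSE)))
  }
  ids <- id_parser(names(aa))
  records <- data.frame(protein_id = ids$protein_id,
                        gene_id = ids$gene_id,
                        sequence = toupper(as.character(aa)),
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  validate_proteome_records(records)
  new_proteome(species_id, records)
}

#' Write a proteome to FASTA
#'
#' @param proteome A \code{proteome} object.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return \code{path}, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path, width = 60L) {
  aa <- Biostrings::AAStringSet(proteome$records$sequence)
  names(aa) <- proteome$records$protein_id
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Keep the longest isoform per gene
#'
#' Before orthology clustering each species' proteome is reduced to one protein
#' per gene — the longest isoform. Length ties are broken deterministically by
#' keeping the lexicographically smallest protein id. The operation is
#' idempotent.
#'
#' @param proteome A \code{proteome} object with gene ids populated.
#' @return A \code{proteome} with exactly one record per gene and
#'   \code{isoform_filtered = TRUE}. Input record order of the kept proteins is
#'   preserved.
#' @export
longest_isoform_filter <- function(proteome) {
  rec <- proteome$records
  if (nrow(rec) == 0L) return(new_proteome(proteome$species_id, rec, TRUE))
  if (any(!nzchar(rec$gene_id))) stop("gene_id must be populated for all records")
  len <- nchar(rec$sequence)
  # order: by gene, then decreasing length, then protein_id; keep first per gene
  ord <- order(rec$gene_id, -len, rec$protein_id)
  first <- !duplicated(rec$gene_id[ord])
  keep_ids <- rec$protein_id[ord][first]
  out <- rec[rec$protein_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  new_proteome(proteome$species_id, out, TRUE)
}
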