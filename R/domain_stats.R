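#' Read a domain-annotation table
#'
#' Two dialects are supported: a simplified TSV with header
#' `protein_id  domain_accession  domain_name  e_value`, and the whitespace-
#' delimited per-domain table emitted by profile-HMM scanners (`domtbl`), from
#' which the query name, domain accession/name and full-sequence E-value are
#' taken.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"domtbl"`.
#' @return data.frame `protein_id`, `domain_accession`, `domain_name`,
#'   `e_value`.
#' @export
read_domain_hits <- function(path, format = c("tsv", "domtbl")) {
  format <- match.arg(format)
  if (format == "tsv") {
    hits <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("protein_id", "domain_accession", "domain_name", "e_value")
    if (!all(need %in% names(hits)))
      stop("domain TSV must have columns: ", paste(need, collapse = ", "))
    return(hits[need])
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(protein_id = character(), domain_accession = character(),
                      domain_name = character(), e_value = numeric(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\\s+")
  # domtblout layout: target name, accession, tlen, query name, ..., col 7 is
  # the full-sequence E-value
  data.frame(protein_id = vapply(f, `[[`, "", 4L),
             domain_accession = vapply(f, `[[`, "", 2L),
             domain_name = vapply(f, `[[`, "", 1L),
             e_value = as.numeric(vapply(f, `[[`, "", 7L)),
             stringsAsFactors = FALSE)
}

#' Filter domain hits at an E-value threshold
#'
#' @param hits data.frame of domain hits (see [read_domain_hits()]).
#' @param e_max Maximum E-value retained (default 1e-6).
#' @return The hits with `e_value <= e_max`, original order preserved.
#' @export
filter_domain_hits <- function(hits, e_max = 1e-6) {
  if (any(hits$e_value < 0)) stop("negative E-value in domain hits")
  hits[hits$e_value <= e_max, , drop = FALSE]
}

strip_accession_version <- function(acc) sub("\\.[0-9]+$", "", acc)

#' Gene-family venom coverage
#'
#' For every domain family: the number of genes in the genome whose protein
#' products carry the domain (`n_genome`), the number of venom proteins
#' carrying it (`n_venom`), and the percentage
#' `100 * n_venom / n_genome` rounded half-up to integer — the proportion of
#' the gene family that is secreted in the venom. The mixed gene-level
#' denominator / protein-level numerator mirrors the conventional reporting;
#' `venom_level = "gene"` forces gene-level counting on both sides.
#'
#' @param genome_hits Domain hits over the whole proteome, already filtered
#'   with [filter_domain_hits()].
#' @param venom_ids Protein ids of the venom catalogue.
#' @param gene_map Named character vector mapping protein_id -> gene_id,
#'   total over the hit proteins.
#' @param venom_level Count venom hits per `"protein"` (default) or per
#'   `"gene"`.
#' @return data.frame `domain_accession` (version suffix stripped),
#'   `domain_name`, `n_genome`, `n_venom`, `pct_in_venom`, sorted by
#'   decreasing percentage.
#' @export
family_coverage <- function(genome_hits, venom_ids, gene_map,
                            venom_level = c("protein", "gene")) {
  venom_level <- match.arg(venom_level)
  hits <- genome_hits
  hits$domain_accession <- strip_accession_version(hits$domain_accession)
  unmapped <- setdiff(unique(hits$protein_id), names(gene_map))
  if (length(unmapped))
    stop("hit protein(s) missing from gene_map: ",
         paste(unmapped, collapse = ", "))
  missing_venom <- setdiff(venom_ids, names(gene_map))
  if (length(missing_venom))
    stop("venom id(s) absent from proteome gene map: ",
         paste(missing_venom, collapse = ", "))
  hits$gene_id <- unname(gene_map[hits$protein_id])
  by_dom <- split(hits, hits$domain_accession)
  out <- do.call(rbind, lapply(by_dom, function(h) {
    n_genome <- length(unique(h$gene_id))
    in_venom <- h[h$protein_id %in% venom_ids, , drop = FALSE]
    n_venom <- if (venom_level == "protein")
      length(unique(in_venom$protein_id)) else length(unique(in_venom$gene_id))
    data.frame(domain_accession = h$domain_accession[1],
               domain_name = h$domain_name[1],
               n_genome = n_genome,
               n_venom = n_venom,
               pct_in_venom = as.integer(round_half_up(100 * n_venom / n_genome)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$pct_in_venom, out$domain_accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
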