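#' Species-group configuration for conservation analysis
#'
#' Declares how comparison species relate to the focal species: a sister group
#' (congeners, e.g. other *Steinernema*), a distant group (e.g.
#' vertebrate-parasitic nematodes) and an `other` bucket for species that are
#' neither (e.g. *Heterorhabditis bacteriophora*): members of `other` never
#' lift a cluster out of the focal-specific category.
#'
#' @param focal Focal species id.
#' @param sister,distant,other Character vectors of species ids; pairwise
#'   disjoint and not containing `focal`.
#' @return A list of class `species_groups`.
#' @export
species_groups <- function(focal, sister, distant, other = character()) {
  all_ids <- c(sister, distant, other)
  if (anyDuplicated(all_ids))
    stop("species groups must be pairwise disjoint")
  if (focal %in% all_ids)
    stop("focal species must not appear in any group")
  structure(list(focal = focal, sister = sister, distant = distant,
                 other = other),
            class = "species_groups")
}

new_ortho_clusters <- function(members, provenance = NA_character_) {
  stopifnot(all(c("cluster_id", "species_id", "protein_id") %in% names(members)))
  key <- paste(members$species_id, members$protein_id, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    # a protein may appear only once across all clusters
    dup_in_two <- unique(members$protein_id[key %in% dup])
    stop("protein(s) present in more than one cluster: ",
         paste(dup_in_two, collapse = ", "))
  }
  structure(list(members = members, provenance = provenance),
            class = "ortho_clusters")
}

#' @export
print.ortho_clusters <- function(x, ...) {
  cat(sprintf("<ortho_clusters> %d clusters, %d members, %d species\n",
              length(unique(x$members$cluster_id)), nrow(x$members),
              length(unique(x$members$species_id))))
  invisible(x)
}

#' Parse an orthology groups file
#'
#' Reads the OrthoMCL-style "groups" text dialect: one cluster per line,
#' `cluster_id: species<sep>protein species<sep>protein ...`.
#'
#' @param path Path to the groups file.
#' @param id_separator Separator between species and protein id in each member
#'   token (default `"|"`).
#' @param species Optional character vector of valid species ids; members from
#'   other species raise an error.
#' @return An `ortho_clusters` object: data.frame `members` with columns
#'   `cluster_id`, `species_id`, `protein_id`.
#' @export
parse_groups <- function(path, id_separator = "|", species = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(new_ortho_clusters(data.frame(cluster_id = character(),
                                         species_id = character(),
                                         protein_id = character(),
                                         stringsAsFactors = FALSE), path))
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(trimws(parts[1])))
      stop("malformed groups line ", i, ": missing 'cluster_id:' prefix")
    cid <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ":")), "\\s+")[[1]]
    if (!length(toks) || !nzchar(toks[1]))
      stop("malformed groups line ", i, ": no members")
    sp <- sub(paste0("\\Q", id_separator, "\\E.*$"), "", toks)
    pr <- sub(paste0("^.*?\\Q", id_separator, "\\E"), "", toks)
    if (any(sp == toks))
      stop("malformed groups line ", i,
           ": member token without separator '", id_separator, "'")
    rows[[i]] <- data.frame(cluster_id = cid, species_id = sp,
                            protein_id = pr, stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, rows)
  if (!is.null(species)) {
    bad <- setdiff(unique(members$species_id), species)
    if (length(bad))
      stop("unknown species in groups file: ", paste(bad, collapse = ", "))
  }
  new_ortho_clusters(members, path)
}

#' Write an orthology cluster set in groups format
#'
#' @param clusters An `ortho_clusters` object.
#' @param path Output path.
#' @param id_separator Separator between species and protein ids.
#' @return `path`, invisibly.
#' @export
write_groups <- function(clusters, path, id_separator = "|") {
  m <- clusters$members
  by_cluster <- split(paste0(m$species_id, id_separator, m$protein_id),
                      m$cluster_id)
  writeLines(paste0(names(by_cluster), ": ",
                    vapply(by_cluster, paste, "", collapse = " ")), path)
  invisible(path)
}

#' Add singleton clusters for unclustered venom proteins
#'
#' Venom proteins absent from every orthology cluster are appended as
#' single-member clusters of the focal species, so that the conservation
#' categories partition the full venom set.
#'
#' @param clusters An `ortho_clusters` object.
#' @param venom_ids Protein ids of the focal species' venom catalogue.
#' @param focal_species Species id to attach the singleton members to.
#' @return An `ortho_clusters` object covering every venom protein.
#' @export
augment_singletons <- function(clusters, venom_ids, focal_species) {
  m <- clusters$members
  present <- m$protein_id[m$species_id == focal_species]
  missing <- setdiff(venom_ids, present)
  if (!length(missing)) return(clusters)
  add <- data.frame(cluster_id = paste0("singleton_", missing),
                    species_id = focal_species,
                    protein_id = missing,
                    stringsAsFactors = FALSE)
  new_ortho_clusters(rbind(m, add), clusters$provenance)
}

#' Categorise venom proteins by conservation
#'
#' Each venom protein inherits a category from its cluster's membership:
#' `distant_conserved` if the cluster holds at least one distant-group protein,
#' else `sister_conserved` if it holds at least one sister-group protein, else
#' `focal_specific`. The precedence distant > sister > specific makes the three
#' categories mutually exclusive; `other`-group members do not affect the call.
#'
#' @param clusters An `ortho_clusters` covering every venom protein (run
#'   [augment_singletons()] first if needed).
#' @param venom_ids Venom protein ids (focal species).
#' @param groups A [species_groups()] configuration.
#' @return data.frame `protein_id`, `cluster_id`, `category` (factor with
#'   levels distant_conserved, sister_conserved, focal_specific).
#' @export
categorize_venom <- function(clusters, venom_ids, groups) {
  m <- clusters$members
  venom_rows <- m[m$species_id == groups$focal & m$protein_id %in% venom_ids, ]
  missing <- setdiff(venom_ids, venom_rows$protein_id)
  if (length(missing))
    stop("venom protein(s) not assigned to any cluster (run ",
         "augment_singletons first): ", paste(missing, collapse = ", "))
  has_distant <- tapply(m$species_id %in% groups$distant, m$cluster_id, any)
  has_sister <- tapply(m$species_id %in% groups$sister, m$cluster_id, any)
  cat_of_cluster <- ifelse(has_distant, "distant_conserved",
                           ifelse(has_sister, "sister_conserved",
                                  "focal_specific"))
  out <- data.frame(protein_id = venom_rows$protein_id,
                    cluster_id = venom_rows$cluster_id,
                    category = factor(cat_of_cluster[venom_rows$cluster_id],
                                      levels = conservation_levels()),
                    stringsAsFactors = FALSE)
  out[order(out$protein_id), , drop = FALSE]
}

conservation_levels <- function() {
  c("distant_conserved", "sister_conserved", "focal_specific")
}

#' Summarise conservation categories
#'
#' @param categories Output of [categorize_venom()].
#' @return data.frame `category`, `n`, `fraction`, `pct` (rounded integer
#'   percent). Counts sum to the venom size.
#' @export
category_summary <- function(categories) {
  if (!nrow(categories)) stop("empty category map")
  n <- as.integer(table(categories$category))
  frac <- n / sum(n)
  data.frame(category = conservation_levels(),
             n = n,
             fraction = frac,
             pct = round_half_up(100 * frac),
             stringsAsFactors = FALSE)
}

#' emPAI-weighted venom composition by conservation category
#'
#' Sums molar fractions within each conservation category — the estimated
#' percentage of venom molecules contributed by distantly conserved,
#' sister-conserved and focal-specific proteins. Because "specific to the
#' focal genus" may pool the sister-conserved and focal-specific slices, the
#' pooled percentage is returned as well.
#'
#' @param categories Output of [categorize_venom()].
#' @param empai_records data.frame with `protein_id` and `molar_fraction`
#'   (see [molar_fractions()]).
#' @return data.frame `category`, `molar_fraction`, `molar_pct`, with
#'   attribute `genus_specific_pct` = sister + focal percentage.
#' @export
venom_molar_breakdown <- function(categories, empai_records) {
  if (!"molar_fraction" %in% names(empai_records))
    stop("empai_records must carry molar_fraction (run molar_fractions first)")
  idx <- match(empai_records$protein_id, categories$protein_id)
  if (anyNA(idx))
    stop("protein(s) with emPAI but no conservation category: ",
         paste(empai_records$protein_id[is.na(idx)], collapse = ", "))
  cat_vec <- factor(categories$category[idx], levels = conservation_levels())
  mf <- tapply(empai_records$molar_fraction, cat_vec, sum, default = 0)
  out <- data.frame(category = conservation_levels(),
                    molar_fraction = as.numeric(mf),
                    molar_pct = 100 * as.numeric(mf),
                    stringsAsFactors = FALSE)
  attr(out, "genus_specific_pct") <-
    sum(out$molar_pct[out$category != "distant_conserved"])
  out
}

#' Rank orthology clusters by venom contribution
#'
#' Per cluster: member counts for every species, the conservation category,
#' the summed molar fraction of its venom members ("fraction of venom"), and
#' the rank (1 = largest fraction; ties broken by cluster id).
#'
#' @param clusters An `ortho_clusters` object.
#' @param categories Output of [categorize_venom()].
#' @param empai_records data.frame with `protein_id` and `molar_fraction`.
#' @return data.frame with one row per cluster containing venom proteins.
#' @export
rank_clusters <- function(clusters, categories, empai_records) {
  m <- clusters$members
  cl_ids <- unique(categories$cluster_id)
  counts <- table(factor(m$cluster_id, levels = cl_ids), m$species_id)
  mf <- empai_records$molar_fraction[
    match(categories$protein_id, empai_records$protein_id)]
  mf[is.na(mf)] <- 0
  frac <- tapply(mf, factor(categories$cluster_id, levels = cl_ids), sum,
                 default = 0)
  cat_of <- categories$category[match(cl_ids, categories$cluster_id)]
  out <- data.frame(cluster_id = cl_ids,
                    as.data.frame.matrix(counts),
                    category = cat_of,
                    fraction_of_venom = as.numeric(frac),
                    stringsAsFactors = FALSE,
                    check.names = FALSE)
  ord <- order(-out$fraction_of_venom, out$cluster_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
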