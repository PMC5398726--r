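#' Synthetic study design with planted truth
#'
#' Builds the parameter set driving every synthetic generator. The defaults
#' mirror the headline shape of an activated-IJ venom study: a focal
#' entomopathogenic nematode with 28,313 genes and 472 venom proteins, 13
#' comparison proteomes (4 congeners, 8 vertebrate-parasitic species, 1
#' entomopathogen outgroup), 321 venom orthology clusters, a five-condition
#' activation time course in two processing batches, Venn-designed DE venom
#' sets (210 upregulated with 135 shared between methods; 88 downregulated
#' with 65 shared), and 79 of 178 time-course DE venom genes planted in 31
#' proximity groups (18 pairs, 9 triplets, 4 quadruplets; mean size 2.55).
#' `scale = "test"` shrinks gene counts and sequence lengths for fast runs
#' while keeping every count that a reported percentage depends on.
#'
#' @param seed Integer master seed; all generators derive their streams from
#'   it, and identical seeds give byte-identical outputs.
#' @param scale `"headline"` (study-shaped sizes) or `"test"` (small).
#' @param ... Named overrides of any design field.
#' @return A list of class `synthetic_design`.
#' @export
synthetic_design <- function(seed = 1L, scale = c("headline", "test"), ...) {
  scale <- match.arg(scale)
  d <- list(
    seed = as.integer(seed),
    species = list(
      focal = "scar",
      sister = c("sfel", "sgla", "smon", "ssca"),
      distant = c("sste", "tcan", "bmal", "hcon",
                  "asuu", "oden", "acey", "dviv"),
      other = "hbac"),
    n_genes_focal = if (scale == "headline") 28313L else 3000L,
    n_genes_other = if (scale == "headline") 8000L else 250L,
    seq_len_range = if (scale == "headline") c(80L, 600L) else c(80L, 300L),
    isoform_probs = c(`1` = 0.7, `2` = 0.2, `3` = 0.07, `4` = 0.03),
    venom_size = 472L,
    n_clusters = 321L,
    category_props = c(distant = 0.43, sister = 0.22, specific = 0.35),
    n_background_clusters = 100L,
    abundance = list(meanlog = 0, sdlog = 1.2),
    detection = list(intercept = 0, slope = 1.5),
    expression = list(
      conditions = c("non_activated", "invitro_12h", "invivo_9h",
                     "invivo_12h", "invivo_15h"),
      replicates = 3L,
      batch2_conditions = c("invivo_9h", "invivo_12h"),
      batch_offset_log2 = 0.8,
      baseline_log2_mean = 5, baseline_log2_sd = 2,
      dispersion = 0.1,
      lfc_range = c(1.2, 3.5),
      venn_up = c(shared = 135L, a_only = 38L, b_only = 37L),
      venn_down = c(shared = 65L, a_only = 12L, b_only = 11L)),
    proximity = list(
      n_query = 178L,
      group_sizes = c(rep(2L, 18), rep(3L, 9), rep(4L, 4)),
      window = 10L),
    domains = data.frame(
      domain_name = c("TILa domain", "Serine carboxypeptidase", "Trypsin",
                      "Ubiquitin-2 like Rad60 SUMO-like",
                      "Trypsin inhibitor-like cysteine-rich domain",
                      "Von Willebrand factor type A domain",
                      "Ubiquitin family", "Eukaryotic aspartyl protease",
                      "Kunitz/Bovine pancreatic trypsin inhibitor domain",
                      "Zinc carboxypeptidase", "Shk domain-like"),
      domain_accession = c("PF12714.2", "PF00450.17", "PF00089.21",
                           "PF11976.3", "PF01826.12", "PF00092.23",
                           "PF00240.18", "PF00026.18", "PF00014.18",
                           "PF00246.19", "PF01549.19"),
      n_genome = c(16L, 24L, 114L, 17L, 79L, 33L, 29L, 39L, 43L, 33L, 85L),
      n_venom = c(9L, 9L, 41L, 6L, 26L, 10L, 7L, 9L, 8L, 6L, 14L),
      stringsAsFactors = FALSE))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(d)) stop("unknown design field: ", nm)
    d[[nm]] <- if (is.list(d[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(d[[nm]], over[[nm]]) else over[[nm]]
  }
  if (abs(sum(d$category_props) - 1) > 1e-9)
    stop("category_props must sum to 1")
  structure(d, class = "synthetic_design")
}

# amino-acid sampling frequencies with natural K/R density so tryptic
# peptides exist at realistic lengths
AA_FREQ <- c(A = 8.3, R = 5.7, N = 4.4, D = 5.4, C = 1.4, Q = 3.9, E = 6.8,
             G = 7.1, H = 2.2, I = 5.8, L = 9.7, K = 5.8, M = 2.4, F = 4.0,
             P = 4.6, S = 7.3, T = 5.6, W = 1.1, Y = 3.3, V = 6.9)

random_sequences <- function(n, len_range) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  res <- sample(names(AA_FREQ), sum(lens), replace = TRUE, prob = AA_FREQ)
  vapply(split(res, rep.int(seq_len(n), lens)), paste, "", collapse = "")
}

make_species_proteome <- function(species_id, n_genes, design,
                                  with_isoforms = TRUE) {
  iso <- if (with_isoforms) {
    sample(as.integer(names(design$isoform_probs)), n_genes, replace = TRUE,
           prob = design$isoform_probs)
  } else rep(1L, n_genes)
  gene_id <- rep(sprintf("%s_g%05d", species_id, seq_len(n_genes)), iso)
  tnum <- unlist(lapply(iso, seq_len), use.names = FALSE)
  protein_id <- sprintf("%s.t%d", gene_id, tnum)
  seqs <- random_sequences(length(protein_id), design$seq_len_range)
  new_proteome(species_id,
               data.frame(protein_id = protein_id, gene_id = gene_id,
                          sequence = unname(seqs), stringsAsFactors = FALSE))
}

plant_positions <- function(design, gene_ids, venom_genes) {
  px <- design$proximity
  query <- venom_genes[seq_len(px$n_query)]
  n_singleton <- px$n_query - sum(px$group_sizes)
  units <- c(lapply(px$group_sizes, identity), as.list(rep(1L, n_singleton)))
  qi <- 0L
  cursor <- 0L
  rows <- list()
  group_truth <- list()
  for (u in units) {
    cursor <- cursor + px$window + sample(3:8, 1)  # > window from previous
    members <- integer(u)
    for (j in seq_len(u)) {
      if (j > 1L) cursor <- cursor + sample(seq_len(px$window), 1)
      members[j] <- cursor
    }
    ids <- query[qi + seq_len(u)]
    qi <- qi + u
    rows[[length(rows) + 1L]] <-
      data.frame(gene_id = ids, ordinal_index = members,
                 stringsAsFactors = FALSE)
    if (u >= 2L) group_truth[[length(group_truth) + 1L]] <- ids
  }
  qpos <- do.call(rbind, rows)
  # fill the remaining ordinal slots of the proximity scaffold with background
  # genes so ordinal indices are dense ranks, then lay the rest out elsewhere
  background <- setdiff(gene_ids, query)
  free_idx <- setdiff(0:max(qpos$ordinal_index), qpos$ordinal_index)
  if (length(free_idx) > length(background))
    stop("infeasible proximity design: scaffold larger than available genes")
  fill <- background[seq_along(free_idx)]
  rest <- background[-seq_along(free_idx)]
  pos <- rbind(
    data.frame(gene_id = c(qpos$gene_id, fill),
               scaffold_id = "scaffold_prox",
               ordinal_index = c(qpos$ordinal_index, free_idx),
               stringsAsFactors = FALSE),
    if (length(rest))
      data.frame(gene_id = rest,
                 scaffold_id = sprintf("scaffold_%03d",
                                       ((seq_along(rest) - 1) %/% 500) + 1),
                 ordinal_index = (seq_along(rest) - 1) %% 500,
                 stringsAsFactors = FALSE))
  rownames(pos) <- NULL
  list(positions = pos, query_genes = query, planted_groups = group_truth)
}

#' Generate synthetic proteomes, gene map and gene positions
#'
#' Emits one proteome per species (the focal species with 1-4 isoforms per
#' gene, comparison species with one), the focal protein-to-gene map, the
#' venom catalogue (longest isoforms of the first `venom_size` focal genes),
#' and a gene-position table in which the planted proximity groups sit within
#' the design window on one scaffold while all other query genes are isolated.
#'
#' @param design A [synthetic_design()].
#' @param out_dir Optional directory; when given, FASTA files, `gene_map.tsv`
#'   and `positions.tsv` are written there.
#' @return List: `proteomes` (named list of `proteome` objects), `gene_map`
#'   (named vector, focal proteins -> genes), `venom_ids`, `positions`,
#'   `proximity_truth` (query genes and planted groups).
#' @export
make_proteomes <- function(design, out_dir = NULL) {
  res <- withr::with_seed(design$seed + 101L, {
    sp <- design$species
    proteomes <- list()
    proteomes[[sp$focal]] <-
      make_species_proteome(sp$focal, design$n_genes_focal, design)
    for (s in c(sp$sister, sp$distant, sp$other))
      proteomes[[s]] <- make_species_proteome(s, design$n_genes_other, design,
                                              with_isoforms = FALSE)
    focal <- proteomes[[sp$focal]]
    filtered <- longest_isoform_filter(focal)
    gene_map <- stats::setNames(focal$records$gene_id,
                                focal$records$protein_id)
    venom_genes <- unique(focal$records$gene_id)[seq_len(design$venom_size)]
    venom_ids <- filtered$records$protein_id[
      match(venom_genes, filtered$records$gene_id)]
    planted <- plant_positions(design, unique(focal$records$gene_id),
                               venom_genes)
    list(proteomes = proteomes, gene_map = gene_map, venom_ids = venom_ids,
         venom_genes = venom_genes, positions = planted$positions,
         proximity_truth = planted[c("query_genes", "planted_groups")])
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in names(res$proteomes))
      write_proteome_fasta(res$proteomes[[s]],
                           file.path(out_dir, paste0(s, ".fa")))
    utils::write.table(
      data.frame(protein_id = names(res$gene_map), gene_id = res$gene_map),
      file.path(out_dir, "gene_map.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$positions, file.path(out_dir, "positions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(res$venom_ids, file.path(out_dir, "venom_ids.txt"))
  }
  res
}

category_counts <- function(design) {
  v <- design$venom_size
  n_distant <- round_half_up(design$category_props[["distant"]] * v)
  n_sister <- round_half_up(design$category_props[["sister"]] * v)
  c(distant_conserved = n_distant, sister_conserved = n_sister,
    focal_specific = v - n_distant - n_sister)
}

#' Generate an orthology cluster set with planted conservation categories
#'
#' Distributes the venom catalogue over `n_clusters` clusters realising the
#' design's category proportions exactly (rounded to counts): every
#' distant-category cluster receives at least one distant-group member,
#' sister-category clusters receive sister members only, and focal-specific
#' clusters hold focal proteins, some alongside outgroup (`other`) members —
#' which must not change their category. Non-venom proteins are padded into
#' background clusters.
#'
#' @param design A [synthetic_design()].
#' @param proteomes Output of [make_proteomes()].
#' @param out_dir Optional directory; writes `groups.txt` and
#'   `category_truth.tsv`.
#' @return List: `clusters` (an `ortho_clusters`), `truth` (data.frame
#'   `protein_id`, `category`), `groups` (the matching [species_groups()]).
#' @export
make_clusters <- function(design, proteomes, out_dir = NULL) {
  res <- withr::with_seed(design$seed + 202L, {
    sp <- design$species
    counts <- category_counts(design)
    venom <- proteomes$venom_ids
    stopifnot(sum(counts) == length(venom))
    cat_of <- rep(names(counts), counts)
    # clusters per category, proportional to venom membership; empty
    # categories get no clusters and the last populated one absorbs slack
    k_cat <- ifelse(counts == 0, 0L,
                    pmax(round(design$n_clusters * counts / sum(counts)), 1L))
    nz <- which(counts > 0)
    last <- nz[length(nz)]
    k_cat[last] <- design$n_clusters - sum(k_cat[-last])
    if (any(k_cat[nz] < 1) || any(k_cat[nz] > counts[nz]))
      stop("infeasible cluster design: adjust n_clusters or venom_size")
    rows <- list()
    truth <- data.frame(protein_id = venom, category = cat_of,
                        stringsAsFactors = FALSE)
    # draw comparison-species proteins without replacement so no protein
    # lands in two clusters (which would silently change cluster categories)
    pools <- stats::setNames(lapply(c(sp$sister, sp$distant, sp$other),
                                    function(s) sample(design$n_genes_other)),
                             c(sp$sister, sp$distant, sp$other))
    pick <- function(species_pool, n) {
      s <- sample(species_pool, n, replace = TRUE)
      idx <- integer(n)
      for (j in seq_len(n)) {
        if (!length(pools[[s[j]]]))
          stop("species pool exhausted: increase n_genes_other")
        idx[j] <- pools[[s[j]]][1]
        pools[[s[j]]] <<- pools[[s[j]]][-1]
      }
      data.frame(species_id = s,
                 protein_id = sprintf("%s_g%05d.t1", s, idx),
                 stringsAsFactors = FALSE)
    }
    ci <- 0L
    vi <- 0L
    for (cat in names(counts)) {
      k <- k_cat[[cat]]
      if (k == 0L) next
      sizes <- rep(counts[[cat]] %/% k, k)
      extra <- counts[[cat]] %% k
      if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      for (s in sizes) {
        ci <- ci + 1L
        cid <- sprintf("VC%04d", ci)
        members <- data.frame(species_id = sp$focal,
                              protein_id = venom[vi + seq_len(s)],
                              stringsAsFactors = FALSE)
        vi <- vi + s
        if (cat == "distant_conserved") {
          members <- rbind(members, pick(sp$distant, sample(1:3, 1)))
          if (stats::runif(1) < 0.4)
            members <- rbind(members, pick(sp$sister, 1L))
        } else if (cat == "sister_conserved") {
          members <- rbind(members, pick(sp$sister, sample(1:3, 1)))
        } else if (stats::runif(1) < 0.25) {
          members <- rbind(members, pick(sp$other, 1L))
        }
        rows[[ci]] <- cbind(cluster_id = cid, members)
      }
    }
    # background clusters of non-venom proteins from sister/distant species
    for (b in seq_len(design$n_background_clusters)) {
      ci <- ci + 1L
      rows[[ci]] <- cbind(cluster_id = sprintf("BG%04d", b),
                          pick(c(sp$sister, sp$distant), sample(2:6, 1)))
    }
    members <- do.call(rbind, rows)
    groups <- species_groups(sp$focal, sp$sister, sp$distant, sp$other)
    list(clusters = new_ortho_clusters(members, "synthetic"),
         truth = truth, groups = groups)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_groups(res$clusters, file.path(out_dir, "groups.txt"))
    utils::write.table(res$truth, file.path(out_dir, "category_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Generate peptide observations driven by planted molar abundances
#'
#' Draws a log-normal molar abundance per protein and observes each of its
#' observable peptides independently with a probability that increases with
#' abundance through a logistic link on the standardised log abundance. emPAI
#' computed from the resulting table rank-recovers the planted abundances.
#'
#' @param design A [synthetic_design()].
#' @param proteome A `proteome` whose records are the candidate proteins.
#' @param dcfg,ocfg Digestion and observability configurations.
#' @param detect_prob Optional fixed detection probability overriding the
#'   abundance-driven logistic model (e.g. 1 for exhaustive observation).
#' @param out_dir Optional directory; writes `peptides.tsv` and
#'   `abundance_truth.tsv`.
#' @return List: `observations` (data.frame `protein_id`, `peptide`,
#'   `n_parent_ions`), `truth` (data.frame `protein_id`, `abundance`,
#'   `n_observable`), `excluded` (proteins with no observable peptide).
#' @export
make_peptide_observations <- function(design, proteome,
                                      dcfg = digestion_config(),
                                      ocfg = observability_config(),
                                      detect_prob = NULL, out_dir = NULL) {
  res <- withr::with_seed(design$seed + 303L, {
    rec <- proteome$records
    n <- nrow(rec)
    ab <- stats::rlnorm(n, design$abundance$meanlog, design$abundance$sdlog)
    z <- (log(ab) - design$abundance$meanlog) / design$abundance$sdlog
    p <- if (is.null(detect_prob))
      stats::plogis(design$detection$intercept + design$detection$slope * z)
    else rep(detect_prob, n)
    obs <- list()
    n_obsbl <- integer(n)
    for (i in seq_len(n)) {
      peps <- unique(digest(rec$sequence[i], dcfg)$peptide)
      if (length(peps))
        peps <- peps[observable_in_window(peptide_mass(peps), ocfg)]
      n_obsbl[i] <- length(peps)
      if (!length(peps)) next
      seen <- peps[stats::runif(length(peps)) < p[i]]
      if (length(seen))
        obs[[length(obs) + 1L]] <- data.frame(
          protein_id = rec$protein_id[i], peptide = seen,
          n_parent_ions = 1L + stats::rpois(length(seen), 0.5),
          stringsAsFactors = FALSE)
    }
    observations <- if (length(obs)) do.call(rbind, obs) else
      data.frame(protein_id = character(), peptide = character(),
                 n_parent_ions = integer(), stringsAsFactors = FALSE)
    list(observations = observations,
         truth = data.frame(protein_id = rec$protein_id, abundance = ab,
                            n_observable = n_obsbl,
                            stringsAsFactors = FALSE),
         excluded = rec$protein_id[n_obsbl == 0L])
  })
  if (length(res$excluded))
    message(length(res$excluded),
            " protein(s) with no observable peptide were excluded")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$observations, file.path(out_dir, "peptides.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$truth, file.path(out_dir, "abundance_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Generate an expression matrix with planted DE, batch and Venn structure
#'
#' Negative-binomial counts for a five-condition activation time course with
#' replicates, a multiplicative batch effect on the later-processed
#' conditions, and differential expression planted on venom genes following
#' the design's Venn layout for two contrasts (in vitro and in vivo activation
#' vs non-activated). Alongside the counts it emits per-contrast DE tables
#' (log2 fold change + FDR, as a DE test would report) in which exactly the
#' planted genes pass the conventional thresholds. With `noise = FALSE` the
#' matrix contains exact log2-scale means (no sampling), for checking that
#' batch-mean removal eliminates the planted offsets completely.
#'
#' @param design A [synthetic_design()].
#' @param gene_ids Optional gene id vector; defaults to focal-style ids of
#'   length `n_genes_focal`.
#' @param noise Draw negative-binomial counts (default) or return exact
#'   log2-scale means.
#' @param out_dir Optional directory; writes `counts.tsv`, `meta.tsv`,
#'   `de_tables.tsv`, `de_truth.tsv`.
#' @return List: `matrix` (genes x samples), `meta` (data.frame `sample_id`,
#'   `condition`, `batch`, `replicate`), `de_tables` (per-contrast results),
#'   `truth` (planted up/down sets per contrast), `venom_genes`.
#' @export
make_expression <- function(design, gene_ids = NULL, noise = TRUE,
                            out_dir = NULL) {
  res <- withr::with_seed(design$seed + 404L, {
    ex <- design$expression
    if (is.null(gene_ids))
      gene_ids <- sprintf("%s_g%05d", design$species$focal,
                          seq_len(design$n_genes_focal))
    n_genes <- length(gene_ids)
    meta <- expand.grid(replicate = seq_len(ex$replicates),
                        condition = ex$conditions,
                        stringsAsFactors = FALSE)
    meta$sample_id <- paste0(meta$condition, "_r", meta$replicate)
    meta$batch <- ifelse(meta$condition %in% ex$batch2_conditions,
                         "batch2", "batch1")
    meta <- meta[c("sample_id", "condition", "batch", "replicate")]
    venom_genes <- gene_ids[seq_len(min(design$venom_size, n_genes))]
    # planted Venn layout over venom genes: contrast A = in vitro 12 h,
    # contrast B = in vivo 15 h, both vs non-activated
    vu <- ex$venn_up; vd <- ex$venn_down
    if (sum(vu) + sum(vd) > length(venom_genes))
      stop("infeasible DE design: Venn sets need ", sum(vu) + sum(vd),
           " genes but only ", length(venom_genes), " venom genes exist")
    pool <- venom_genes
    take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
    up_shared <- take(vu[["shared"]]); up_a <- take(vu[["a_only"]])
    up_b <- take(vu[["b_only"]])
    down_shared <- take(vd[["shared"]]); down_a <- take(vd[["a_only"]])
    down_b <- take(vd[["b_only"]])
    truth <- list(
      up_invitro = c(up_shared, up_a), up_invivo = c(up_shared, up_b),
      down_invitro = c(down_shared, down_a),
      down_invivo = c(down_shared, down_b))
    lfc_of <- function(genes, sign) {
      stats::setNames(sign * stats::runif(length(genes),
                                          ex$lfc_range[1], ex$lfc_range[2]),
                      genes)
    }
    eff <- list(
      invitro_12h = c(lfc_of(truth$up_invitro, 1),
                      lfc_of(truth$down_invitro, -1)),
      invivo_15h = c(lfc_of(truth$up_invivo, 1),
                     lfc_of(truth$down_invivo, -1)))
    base <- stats::rnorm(n_genes, ex$baseline_log2_mean, ex$baseline_log2_sd)
    names(base) <- gene_ids
    log2mu <- matrix(base, n_genes, nrow(meta),
                     dimnames = list(gene_ids, meta$sample_id))
    for (contrast in names(eff)) {
      cols <- meta$sample_id[meta$condition == contrast]
      e <- eff[[contrast]]
      log2mu[names(e), cols] <- log2mu[names(e), cols] + e
    }
    log2mu[, meta$batch == "batch2"] <-
      log2mu[, meta$batch == "batch2"] + ex$batch_offset_log2
    m <- if (noise) {
      counts <- matrix(stats::rnbinom(length(log2mu), mu = 2^log2mu,
                                      size = 1 / ex$dispersion),
                       n_genes, nrow(meta), dimnames = dimnames(log2mu))
      counts
    } else log2mu
    # per-contrast DE tables as a count-based test would report them:
    # planted genes pass FDR < 0.05 and |log2FC| > 1, everything else fails
    de <- do.call(rbind, lapply(names(eff), function(contrast) {
      e <- eff[[contrast]]
      lfc <- stats::setNames(stats::rnorm(n_genes, 0, 0.25), gene_ids)
      lfc <- pmin(pmax(lfc, -0.95), 0.95)
      fdr <- stats::setNames(stats::runif(n_genes, 0.05, 1), gene_ids)
      lfc[names(e)] <- e
      fdr[names(e)] <- stats::runif(length(e), 1e-8, 0.049)
      data.frame(gene_id = gene_ids, log2fc = unname(lfc),
                 fdr = unname(fdr), contrast = contrast,
                 stringsAsFactors = FALSE)
    }))
    list(matrix = m, meta = meta, de_tables = de, truth = truth,
         venom_genes = venom_genes)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(gene_id = rownames(res$matrix), res$matrix,
                                  check.names = FALSE),
                       file.path(out_dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$meta, file.path(out_dir, "meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$de_tables, file.path(out_dir, "de_tables.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth_df <- do.call(rbind, lapply(names(res$truth), function(nm)
      data.frame(set = nm, gene_id = res$truth[[nm]],
                 stringsAsFactors = FALSE)))
    utils::write.table(truth_df, file.path(out_dir, "de_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Generate domain hits realising designed family coverage counts
#'
#' For every domain family in the design, creates that family's genome genes
#' (one protein each) with a significant hit, marks the designed number of
#' them as venom proteins, and adds decoy hits above the E-value threshold to
#' exercise filtering.
#'
#' @param design A [synthetic_design()].
#' @param out_dir Optional directory; writes `domain_hits.tsv`,
#'   `domain_venom_ids.txt`, `domain_gene_map.tsv`.
#' @return List: `hits`, `venom_ids`, `gene_map`, `truth` (the design table).
#' @export
make_domain_hits <- function(design, out_dir = NULL) {
  res <- withr::with_seed(design$seed + 505L, {
    dm <- design$domains
    rows <- list(); venom <- character(); gene_map <- character()
    for (i in seq_len(nrow(dm))) {
      genes <- sprintf("dom%02d_g%03d", i, seq_len(dm$n_genome[i]))
      prots <- paste0(genes, ".t1")
      gene_map[prots] <- genes
      venom <- c(venom, prots[seq_len(dm$n_venom[i])])
      rows[[i]] <- data.frame(
        protein_id = prots,
        domain_accession = dm$domain_accession[i],
        domain_name = dm$domain_name[i],
        e_value = 10^(-stats::runif(length(prots), 7, 40)),
        stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, rows)
    decoys <- hits[sample(nrow(hits), min(50L, nrow(hits))), ]
    decoys$domain_accession <- "PF99999.1"
    decoys$domain_name <- "decoy domain"
    decoys$e_value <- stats::runif(nrow(decoys), 1e-5, 1e-2)
    hits <- rbind(hits, decoys)
    hits <- hits[sample(nrow(hits)), ]
    rownames(hits) <- NULL
    list(hits = hits, venom_ids = venom, gene_map = gene_map, truth = dm)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$hits, file.path(out_dir, "domain_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(res$venom_ids, file.path(out_dir, "domain_venom_ids.txt"))
    utils::write.table(
      data.frame(protein_id = names(res$gene_map), gene_id = res$gene_map),
      file.path(out_dir, "domain_gene_map.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Generate RNA-protein pairs with a planted rank correlation
#'
#' Bivariate-normal latent scores with the Pearson correlation that implies
#' the requested Spearman correlation (`r = 2 sin(pi * rho / 6)`), mapped to a
#' positive expression scale and a log-normal abundance scale (rank
#' correlation is unchanged by the monotone maps).
#'
#' @param design A [synthetic_design()].
#' @param n Number of gene-protein pairs.
#' @param rho Target Spearman correlation.
#' @return data.frame `gene_id`, `protein_id`, `expression`, `empai`.
#' @export
make_rna_protein_pairs <- function(design, n = 100L, rho = 0.34) {
  withr::with_seed(design$seed + 606L, {
    r <- 2 * sin(pi * rho / 6)
    x <- stats::rnorm(n)
    y <- r * x + sqrt(1 - r^2) * stats::rnorm(n)
    data.frame(gene_id = sprintf("g%04d", seq_len(n)),
               protein_id = sprintf("g%04d.t1", seq_len(n)),
               expression = 2^(5 + 2 * x),
               empai = exp(y),
               stringsAsFactors = FALSE)
  })
}

#' Generate activation-rate count data
#'
#' Per-replicate worm counts (non-activated / partially / fully activated)
#' over a time course, with the activated fraction rising along a logistic
#' curve and binomial sampling noise across replicates.
#'
#' @param design A [synthetic_design()].
#' @param time_points Hours post induction.
#' @param n_replicates Replicates per time point.
#' @param n_worms Worms scored per replicate.
#' @return data.frame `time_h`, `replicate`, `n_non`, `n_partial`, `n_full`.
#' @export
make_activation_counts <- function(design, time_points = c(0, 3, 6, 9, 12, 24),
                                   n_replicates = 3L, n_worms = 100L) {
  withr::with_seed(design$seed + 707L, {
    rows <- list()
    for (t in time_points) {
      p_act <- stats::plogis((t - 6) / 2.5) * 0.9
      for (r in seq_len(n_replicates)) {
        n_act <- stats::rbinom(1, n_worms, p_act)
        n_full <- stats::rbinom(1, n_act, stats::plogis((t - 9) / 3))
        rows[[length(rows) + 1L]] <- data.frame(
          time_h = t, replicate = r,
          n_non = n_worms - n_act, n_partial = n_act - n_full,
          n_full = n_full)
      }
    }
    do.call(rbind, rows)
  })
}
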