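#' Log2(x + 1) transform of an expression matrix
#'
#' @param m Numeric matrix, genes x samples, non-negative.
#' @return Matrix of the same shape with each value `log2(x + 1)`.
#' @export
log_transform <- function(m) {
  if (any(m < 0)) stop("expression values must be non-negative")
  log2(m + 1)
}

#' Remove per-gene batch means
#'
#' Technical batch correction on the log scale: for every gene, each batch's
#' mean is shifted onto the gene's grand mean, leaving within-batch deviations
#' untouched. Equivalent to regressing out a batch indicator with no other
#' covariates.
#'
#' @param m Log-scale matrix, genes x samples.
#' @param batch Batch label per sample (length = ncol(m)).
#' @return Corrected matrix.
#' @export
remove_batch_means <- function(m, batch) {
  if (length(batch) != ncol(m))
    stop("batch must have one label per sample")
  batch <- as.factor(batch)
  if (any(table(batch) == 0L)) stop("batch with zero samples")
  grand <- rowMeans(m)
  out <- m
  for (b in levels(batch)) {
    idx <- which(batch == b)
    out[, idx] <- m[, idx, drop = FALSE] -
      rowMeans(m[, idx, drop = FALSE]) + grand
  }
  out
}

#' Quantile-normalise samples
#'
#' Forces every sample (column) onto the common reference distribution — the
#' row-wise mean of the sorted columns — while preserving within-sample ranks;
#' ties receive the mean of the reference values at their tied ranks.
#'
#' @param m Numeric matrix, genes x samples (>= 2 samples).
#' @return Quantile-normalised matrix.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2L) stop("need at least two samples")
  out <- limma::normalizeQuantiles(as.matrix(m), ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Sample Spearman-correlation matrix with k-means clustering
#'
#' Spearman rank correlations between samples over all genes, then k-means
#' (seeded, 50 restarts) on the rows of the correlation matrix to group
#' samples with similar correlation profiles.
#'
#' @param m Transformed matrix, genes x samples.
#' @param k Number of sample clusters.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return List: `correlation` (symmetric, unit diagonal) and `clusters`
#'   (named integer vector of sample labels).
#' @export
sample_correlation_clusters <- function(m, k, seed = 1L, nstart = 50L) {
  if (ncol(m) < 2L) stop("need at least two samples")
  if (k > ncol(m)) stop("k must not exceed the number of samples")
  cm <- stats::cor(m, method = "spearman")
  cl <- withr::with_seed(seed, stats::kmeans(cm, centers = k, nstart = nstart))
  list(correlation = cm, clusters = cl$cluster)
}

#' PCA of samples
#'
#' Centred principal component analysis with samples as observations and
#' genes as variables.
#'
#' @param m Transformed matrix, genes x samples.
#' @param n_components Number of components to return.
#' @return List: `coordinates` (samples x components) and
#'   `variance_fraction` (per returned component, of total variance).
#' @export
sample_pca <- function(m, n_components = 2L) {
  if (ncol(m) < 2L) stop("need at least two samples")
  x <- t(m)
  if (all(apply(x, 2, function(v) diff(range(v)) == 0)))
    stop("degenerate matrix: all samples identical")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(p$x))
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x[, seq_len(n_components), drop = FALSE],
       variance_fraction = vf[seq_len(n_components)])
}

#' Threshold differential-expression calls
#'
#' Applies the conventional cut: a gene is upregulated if `fdr < fdr_max` and
#' its fold change exceeds `fold_change_min` (i.e. `log2fc > log2(fold_change_min)`,
#' strict), downregulated symmetrically.
#'
#' @param results data.frame with columns `gene_id`, `log2fc`, `fdr`.
#' @param fdr_max FDR threshold (default 0.05, strict `<`).
#' @param fold_change_min Fold-change threshold (default 2, strict `>`).
#' @return List of character vectors `up` and `down` (disjoint).
#' @export
de_threshold_filter <- function(results, fdr_max = 0.05, fold_change_min = 2) {
  lfc_min <- log2(fold_change_min)
  sig <- results$fdr < fdr_max
  list(up = results$gene_id[sig & results$log2fc > lfc_min],
       down = results$gene_id[sig & results$log2fc < -lfc_min])
}

#' Overlap statistics between two gene sets
#'
#' Venn-style summary; the shared percentage is taken relative to the union of
#' the two sets and rounded half-up to integer.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @return List: `shared`, `a_only`, `b_only`, `total_union` (counts) and
#'   `pct_shared`.
#' @export
overlap_stats <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) && !length(set_b)) stop("both sets are empty")
  shared <- length(intersect(set_a, set_b))
  uni <- length(union(set_a, set_b))
  list(shared = shared,
       a_only = length(setdiff(set_a, set_b)),
       b_only = length(setdiff(set_b, set_a)),
       total_union = uni,
       pct_shared = as.integer(round_half_up(100 * shared / uni)))
}

#' Mean-centre gene rows
#'
#' @param m Numeric matrix, genes x samples.
#' @return Matrix with every row shifted to mean zero (heatmap-ready).
#' @export
mean_center_rows <- function(m) {
  m - rowMeans(m)
}

#' Genomic proximity groups (operon-like organisation)
#'
#' Chains genes of interest into groups when their ordinal positions along a
#' scaffold are within `window` genes of each other: within each scaffold the
#' queried genes are sorted by ordinal index and consecutive genes with gap
#' <= `window` are linked transitively (single linkage). Singletons are not
#' groups; the summary counts only genes in groups of size >= 2.
#'
#' @param genes Character vector of gene ids to test.
#' @param positions data.frame `gene_id`, `scaffold_id`, `ordinal_index`
#'   (gene's rank along its scaffold).
#' @param window Maximum ordinal gap linking two genes (default 10).
#' @return List: `groups` — data.frame `group_id`, `gene_id`, `scaffold_id`,
#'   `ordinal_index` — and `summary` with `n_genes`, `n_clustered`,
#'   `fraction_clustered`, `pct_clustered`, `n_groups`, `mean_group_size`.
#' @export
proximity_groups <- function(genes, positions, window = 10L) {
  genes <- unique(genes)
  idx <- match(genes, positions$gene_id)
  if (anyNA(idx))
    stop("gene(s) without a position: ",
         paste(genes[is.na(idx)], collapse = ", "))
  pos <- positions[idx, , drop = FALSE]
  groups <- list()
  for (sc in unique(pos$scaffold_id)) {
    p <- pos[pos$scaffold_id == sc, , drop = FALSE]
    p <- p[order(p$ordinal_index), , drop = FALSE]
    if (nrow(p) < 2L) next
    gap <- diff(p$ordinal_index)
    grp <- cumsum(c(0L, gap > window))
    for (g in split(p, grp)) {
      if (nrow(g) >= 2L) groups[[length(groups) + 1L]] <- g
    }
  }
  if (length(groups)) {
    tab <- do.call(rbind, Map(function(g, i) {
      data.frame(group_id = sprintf("pg%03d", i),
                 gene_id = g$gene_id,
                 scaffold_id = g$scaffold_id,
                 ordinal_index = g$ordinal_index,
                 stringsAsFactors = FALSE)
    }, groups, seq_along(groups)))
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(group_id = character(), gene_id = character(),
                      scaffold_id = character(), ordinal_index = integer(),
                      stringsAsFactors = FALSE)
  }
  n_clustered <- nrow(tab)
  sizes <- if (length(groups)) vapply(groups, nrow, integer(1)) else integer()
  list(groups = tab,
       summary = list(
         n_genes = length(genes),
         n_clustered = n_clustered,
         fraction_clustered = n_clustered / length(genes),
         pct_clustered = as.integer(
           round_half_up(100 * n_clustered / length(genes))),
         n_groups = length(groups),
         mean_group_size = if (length(sizes)) mean(sizes) else NA_real_))
}

#' Spearman correlation between transcript and protein abundance
#'
#' Correlates per-gene expression with emPAI protein abundance over the
#' `top_n` most abundant proteins.
#'
#' @param expression Named numeric vector of per-gene expression values.
#' @param abundance data.frame with `protein_id` and `empai`.
#' @param gene_map Named character vector protein_id -> gene_id, total over
#'   the selected proteins.
#' @param top_n Number of top proteins by emPAI to use (default 100).
#' @return Spearman rho over the selected pairs.
#' @export
rna_protein_correlation <- function(expression, abundance, gene_map,
                                    top_n = 100L) {
  ab <- abundance[order(-abundance$empai, abundance$protein_id), , drop = FALSE]
  ab <- utils::head(ab, top_n)
  genes <- unname(gene_map[ab$protein_id])
  if (anyNA(genes))
    stop("protein(s) without a gene mapping: ",
         paste(ab$protein_id[is.na(genes)], collapse = ", "))
  expr <- expression[genes]
  if (anyNA(expr))
    stop("gene(s) without expression values: ",
         paste(genes[is.na(expr)], collapse = ", "))
  if (length(expr) < 3L) stop("need at least 3 RNA-protein pairs")
  unname(stats::cor(expr, ab$empai, method = "spearman"))
}
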