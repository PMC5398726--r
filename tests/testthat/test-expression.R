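test_that("log2(x+1) transform is invertible and rejects negatives", {
  expect_equal(log_transform(matrix(c(0, 1, 3), 1)),
               matrix(c(0, 1, 2), 1))
  withr::with_seed(2, m <- matrix(rexp(60, 0.01), 10, 6))
  expect_equal(2^log_transform(m) - 1, m, tolerance = 1e-9)
  expect_error(log_transform(matrix(-1)), "non-negative")
})

test_that("batch-mean removal centres each batch on the gene grand mean", {
  m <- matrix(c(5, 5, 7, 7), 1, 4)
  out <- remove_batch_means(m, c("a", "a", "b", "b"))
  expect_equal(out, matrix(c(6, 6, 6, 6), 1, 4))
  # planted per-batch offsets vanish completely
  withr::with_seed(4, {
    base <- matrix(rnorm(200, 8, 2), 20, 10)
    batch <- rep(c("b1", "b2"), each = 5)
    off <- ifelse(batch == "b2", 1.7, 0)
    shifted <- sweep(base, 2, off, `+`)
    out <- remove_batch_means(shifted, batch)
    diffs <- rowMeans(out[, batch == "b1"]) - rowMeans(out[, batch == "b2"])
    expect_true(all(abs(diffs) < 1e-9))
    # within-batch deviations preserved
    dev_in <- shifted[, 1:5] - rowMeans(shifted[, 1:5])
    dev_out <- out[, 1:5] - rowMeans(out[, 1:5])
    expect_equal(dev_in, dev_out, tolerance = 1e-12)
  })
  expect_error(remove_batch_means(m, c("a", "a")), "one label")
})

test_that("quantile normalization equalises column distributions", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))
  # rank order preserved, sorted columns identical, on random matrices
  withr::with_seed(6, {
    for (i in 1:5) {
      m <- matrix(rlnorm(300), 50, 6)
      out <- quantile_normalize(m)
      sorted <- apply(out, 2, sort)
      expect_true(max(sorted - sorted[, 1]) < 1e-9)
      for (j in 1:6) expect_equal(order(out[, j]), order(m[, j]))
    }
  })
  # already-identical samples are unchanged
  m <- matrix(rep(c(1, 5, 9), 3), 3, 3)
  expect_equal(quantile_normalize(m), m)
})

test_that("sample correlation matrix is symmetric and recovers planted groups", {
  withr::with_seed(12, {
    # two sample groups expressing distinct gene programs
    prog <- matrix(rnorm(200, 5, 0.2), 100, 2)
    m <- cbind(prog[, c(1, 1, 1)] + rnorm(300, 0, 0.05),
               prog[, c(2, 2, 2)] + rnorm(300, 0, 0.05))
    m[1:50, 4:6] <- m[1:50, 4:6] + 4   # group-2 program
    colnames(m) <- paste0("s", 1:6)
  })
  res <- sample_correlation_clusters(m, k = 2)
  expect_equal(res$correlation, t(res$correlation))
  expect_equal(unname(diag(res$correlation)), rep(1, 6))
  expect_equal(length(unique(res$clusters[1:3])), 1)
  expect_equal(length(unique(res$clusters[4:6])), 1)
  expect_false(res$clusters[1] == res$clusters[4])
  # duplicated sample -> correlation 1; rank reversal -> -1
  m2 <- cbind(a = 1:10, b = 1:10, c = 10:1)
  cc <- sample_correlation_clusters(m2, k = 1)$correlation
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
  expect_error(sample_correlation_clusters(m2, k = 5), "k must not exceed")
})

test_that("sample PCA orders a planted gradient and bounds variance fractions", {
  withr::with_seed(14, {
    grad <- seq(0, 5, length.out = 8)
    m <- outer(rnorm(100, 0, 1), grad) + matrix(rnorm(800, 0, 0.01), 100, 8)
    colnames(m) <- paste0("s", 1:8)
  })
  p <- sample_pca(m, 3)
  ord <- order(p$coordinates[, 1])
  expect_true(identical(ord, 1:8) || identical(ord, 8:1))
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_lte(sum(p$variance_fraction), 1 + 1e-12)
  # two samples: all variance on PC1
  p2 <- sample_pca(m[, 1:2], 2)
  expect_equal(p2$variance_fraction[1], 1)
  expect_error(sample_pca(matrix(1, 5, 3)), "degenerate")
})

test_that("DE thresholding applies strict FDR and fold-change cuts", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(1.5, 0.9, -1.2, -3),
                    fdr = c(0.04, 0.04, 0.2, 0.001))
  de <- de_threshold_filter(res)
  expect_equal(de$up, "a")     # b fails fold change, 2^0.9 < 2
  expect_equal(de$down, "d")   # c fails FDR
  # brute-force oracle on random tables; up/down disjoint
  withr::with_seed(16, {
    for (i in 1:5) {
      r <- data.frame(gene_id = sprintf("g%d", 1:200),
                      log2fc = rnorm(200, 0, 2), fdr = runif(200))
      de <- de_threshold_filter(r)
      expect_setequal(de$up, r$gene_id[r$fdr < 0.05 & r$log2fc > 1])
      expect_setequal(de$down, r$gene_id[r$fdr < 0.05 & r$log2fc < -1])
      expect_length(intersect(de$up, de$down), 0)
    }
  })
})

test_that("overlap statistics report union-based shared percentages", {
  o <- overlap_stats(letters[1:5], letters[1:5])
  expect_equal(o$pct_shared, 100L)
  # published-style worked examples: 135 of 210 and 65 of 88
  a <- sprintf("u%03d", 1:173); b <- sprintf("u%03d", c(1:135, 174:210))
  o <- overlap_stats(a, b)
  expect_equal(o$shared, 135); expect_equal(o$total_union, 210)
  expect_equal(o$pct_shared, 64L)
  a <- sprintf("d%03d", 1:77); b <- sprintf("d%03d", c(1:65, 78:88))
  o <- overlap_stats(a, b)
  expect_equal(o$pct_shared, 74L)
  expect_equal(o$shared + o$a_only + o$b_only, o$total_union)
  expect_error(overlap_stats(character(), character()), "empty")
})

test_that("row mean-centering zeroes every gene mean", {
  expect_equal(mean_center_rows(matrix(c(1, 2, 3), 1)),
               matrix(c(-1, 0, 1), 1))
  withr::with_seed(18, m <- matrix(rnorm(100, 10), 10, 10))
  expect_true(all(abs(rowMeans(mean_center_rows(m))) < 1e-12))
})

test_that("proximity grouping chains genes within the window per scaffold", {
  pos <- data.frame(gene_id = c("a", "b", "c"),
                    scaffold_id = "s1", ordinal_index = c(5, 12, 40))
  px <- proximity_groups(c("a", "b", "c"), pos, window = 10)
  expect_equal(sort(px$groups$gene_id), c("a", "b"))
  expect_equal(px$summary$n_groups, 1)
  expect_equal(px$summary$mean_group_size, 2)
  expect_equal(px$summary$fraction_clustered, 2 / 3, tolerance = 1e-12)
  # genes on distinct scaffolds never group
  pos2 <- data.frame(gene_id = c("a", "b"),
                     scaffold_id = c("s1", "s2"), ordinal_index = c(1, 2))
  expect_equal(proximity_groups(c("a", "b"), pos2)$summary$n_clustered, 0)
  expect_error(proximity_groups(c("a", "zz"), pos), "zz")
})

test_that("proximity grouping equals the graph transitive-closure oracle", {
  withr::with_seed(23, {
    for (i in 1:15) {
      n <- 30
      pos <- data.frame(gene_id = sprintf("g%02d", 1:n),
                        scaffold_id = sample(c("s1", "s2", "s3"), n, TRUE),
                        ordinal_index = sample(0:120, n))
      w <- sample(c(3, 10, 25), 1)
      got <- proximity_groups(pos$gene_id, pos, window = w)
      want <- proximity_oracle(pos$gene_id, pos, window = w)
      got_groups <- split(got$groups$gene_id, got$groups$group_id)
      expect_identical(canonical_groups(got_groups), canonical_groups(want))
      # order invariance
      shuf <- proximity_groups(sample(pos$gene_id), pos, window = w)
      expect_identical(canonical_groups(split(shuf$groups$gene_id,
                                              shuf$groups$group_id)),
                       canonical_groups(got_groups))
      # every member is within the window of another member
      for (g in got_groups) {
        idx <- pos$ordinal_index[match(g, pos$gene_id)]
        expect_true(all(vapply(seq_along(idx), function(j)
          any(abs(idx[j] - idx[-j]) <= w), logical(1))))
      }
    }
  })
})

test_that("RNA-protein correlation hits the closed-form extremes", {
  ab <- data.frame(protein_id = sprintf("p%02d", 1:20), empai = 20:1)
  map <- stats::setNames(sprintf("g%02d", 1:20), ab$protein_id)
  expr_same <- stats::setNames(as.numeric(20:1), map)
  expect_equal(rna_protein_correlation(expr_same, ab, map, top_n = 20), 1)
  expr_rev <- stats::setNames(as.numeric(1:20), map)
  expect_equal(rna_protein_correlation(expr_rev, ab, map, top_n = 20), -1)
  expect_error(rna_protein_correlation(expr_same[1:2], ab[1:2, ], map, 2),
               "at least 3")
})

test_that("a planted rank correlation of 0.34 is estimated within tolerance", {
  rhos <- vapply(1:10, function(s) {
    pairs <- make_rna_protein_pairs(synthetic_design(seed = s), n = 100,
                                    rho = 0.34)
    rna_protein_correlation(
      stats::setNames(pairs$expression, pairs$gene_id),
      pairs[, c("protein_id", "empai")],
      stats::setNames(pairs$gene_id, pairs$protein_id), top_n = 100)
  }, numeric(1))
  expect_true(all(abs(rhos - 0.34) < 0.3))
  expect_lt(abs(mean(rhos) - 0.34), 0.15)
})
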