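# Independent oracles used across test files. Each recomputes the quantity
# under test from first principles, by a different route than the package.

# exhaustive digestion oracle: every (start, end) substring is a peptide iff
# it is bounded by cleavage sites or termini, retains <= max_missed internal
# sites, and is long enough
digest_oracle <- function(sequence, max_missed = 2L, min_len = 6L,
                          proline_exception = "R") {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  site_after <- logical(n)
  for (i in seq_len(n - 1)) {
    if (res[i] %in% c("K", "R")) {
      blocked <- res[i + 1] == "P" &&
        res[i] %in% strsplit(proline_exception, "")[[1]]
      site_after[i] <- !blocked
    }
  }
  out <- list()
  for (start in 1:n) {
    if (start > 1 && !site_after[start - 1]) next
    for (end in start:n) {
      if (end < n && !site_after[end]) next
      if (end - start + 1 < min_len) next
      internal <- if (end > start) sum(site_after[start:(end - 1)]) else 0L
      if (internal > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(res[start:end], collapse = ""),
        missed_cleavages = internal, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(peptide = character(),
                                      missed_cleavages = integer()))
  unique(do.call(rbind, out))
}

# peptide monoisotopic mass from elemental composition (independent of the
# package's residue-mass table); C carries carbamidomethyl (+C2H3NO)
mass_oracle <- function(peptide) {
  el <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
          O = 15.9949146221, S = 31.97207069)
  comp <- list( # residue formulas as c(C, H, N, O, S)
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3 + 2, 5 + 3, 1 + 1, 1 + 1, 1), L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0), N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0), K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1), H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0),
    R = c(6, 12, 4, 1, 0), Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
  res <- strsplit(peptide, "")[[1]]
  tot <- Reduce(`+`, comp[res])
  sum(tot * el[c("C", "H", "N", "O", "S")]) + 2 * el["H"] + el["O"]
}

# transitive-closure oracle for proximity grouping: connected components of
# the gap graph (same scaffold, ordinal distance <= window), sizes >= 2
proximity_oracle <- function(genes, positions, window) {
  pos <- positions[match(genes, positions$gene_id), ]
  n <- nrow(pos)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    pos$scaffold_id[i] == pos$scaffold_id[j] &
      abs(pos$ordinal_index[i] - pos$ordinal_index[j]) <= window)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  groups <- split(pos$gene_id, comp)
  Filter(function(g) length(g) >= 2, groups)
}

# canonical form for comparing group partitions regardless of labels/order
canonical_groups <- function(groups) {
  g <- lapply(groups, function(x) sort(x))
  unname(g[order(vapply(g, `[`, "", 1))])
}

random_aa_seq <- function(len, kr_rate = 0.12) {
  aa <- c("A", "G", "L", "S", "V", "T", "E", "D", "P", "N", "F", "Y")
  s <- sample(aa, len, replace = TRUE)
  n_kr <- rbinom(1, len, kr_rate)
  if (n_kr > 0)
    s[sample(len, n_kr)] <- sample(c("K", "R"), n_kr, replace = TRUE)
  paste(s, collapse = "")
}
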