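# Independent brute-force oracles, deliberately naive: they share no code
# with the package internals they check.

# Average ranks by counting smaller/equal elements.
brute_ranks <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

# Pearson correlation from raw sums.
brute_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# Tie-corrected Spearman correlation: Pearson on average ranks.
brute_spearman <- function(a, b) brute_pearson(brute_ranks(a), brute_ranks(b))

# Empirical FDR by double loop over thresholds.
brute_fdr <- function(observed, null_values, p, mode = "empirical") {
  vapply(observed, function(z) {
    i <- sum(observed >= z)
    n <- sum(null_values >= z)
    if (mode == "empirical") {
      if (n == 0) 0 else min(1, n / (i * p))
    } else {
      if (n == 0) Inf else i * p / n
    }
  }, numeric(1))
}

# Rank-sum AUC of a score for a binary label.
brute_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Two-sample Kolmogorov-Smirnov statistic by explicit ECDF difference.
brute_ks <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

# Build a sync_records object from per-pool count strings ("A:T:C:G:N:del").
make_sync <- function(contig, pos, ref, pool_strings, design) {
  lines <- paste(contig, pos, ref,
                 apply(pool_strings, 1, paste, collapse = "\t"), sep = "\t")
  path <- tempfile(fileext = ".sync")
  writeLines(lines, path)
  read_sync(path, design)
}

# A one-record sync_records object around a given counts array.
sync_records_for_test <- function(counts) {
  structure(list(
    meta = data.frame(contig = rep("TRX1", dim(counts)[1]),
                      pos = seq_len(dim(counts)[1]),
                      ref = rep("A", dim(counts)[1]),
                      stringsAsFactors = FALSE),
    counts = counts), class = "sync_records")
}

# A covariance model with identity whitening, for closed-form limit checks.
identity_model <- function(S) {
  structure(list(omega = diag(S), omega_shrunk = diag(S),
                 chol_lower = diag(S), lambda = 0, n_snps_used = S),
            class = "covariance_model")
}

# A null distribution built directly from given values.
make_null <- function(snp_null, p, gene_null = numeric(0),
                      genes = character(0)) {
  structure(list(p = p, seed = NA_integer_, snp_null = snp_null,
                 gene_null = gene_null, genes = genes,
                 n_scored_per_perm = NA_integer_),
            class = "null_distribution")
}
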