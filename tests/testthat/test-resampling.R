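design9 <- default_pool_design()
std_env <- environment_vector(rep(c(0, 1, 2), each = 3), design9,
                              standardize = TRUE)

test_that("environment permutations preserve the multiset and the seed", {
  perms <- permute_environment(std_env, p = 2, seed = 1)
  expect_equal(dim(perms), c(2L, 9L))
  for (i in 1:2) expect_equal(sort(perms[i, ]), sort(std_env$values))
  expect_identical(perms, permute_environment(std_env, p = 2, seed = 1))
  expect_false(identical(perms,
                         permute_environment(std_env, p = 2, seed = 2)))
})

test_that("permutation is exchangeable: per-position means approach zero", {
  perms <- permute_environment(std_env, p = 10000, seed = 42)
  # each column is a mean of 10^4 draws from a mean-zero multiset
  expect_true(all(abs(colMeans(perms)) < 4 / sqrt(10000)))
})

test_that("permuting leaves global RNG state untouched", {
  set.seed(123)
  expected <- runif(1)
  set.seed(123)
  invisible(permute_environment(std_env, p = 5, seed = 9))
  expect_identical(runif(1), expected)
})

test_that("null distribution pools p x K scores and is seed-reproducible", {
  set.seed(31)
  x <- matrix(rnorm(27), 3, 9)
  std <- structure(list(x = x, p_bar = rep(0.5, 3), usable = rep(TRUE, 3)),
                   class = "standardized_freqs")
  model <- identity_model(9)
  null <- build_null(std, model, std_env, genes = rep("g1", 3),
                     p = 2, seed = 8372, min_snps = 3)
  expect_equal(length(null$snp_null), 6L)           # 3 SNPs x 2 perms
  expect_equal(null$genes, "g1")
  expect_equal(length(null$gene_null), 2L)          # 1 gene x 2 perms
  null2 <- build_null(std, model, std_env, genes = rep("g1", 3),
                      p = 2, seed = 8372, min_snps = 3)
  expect_identical(null$snp_null, null2$snp_null)
  expect_error(build_null(std, model, std_env, genes = rep("g1", 3), p = 0),
               "")
})

test_that("SNP-level FDR reproduces the hand-worked example in both modes", {
  observed <- c(0.8, 0.6)
  null <- make_null(c(rep(0.7, 39), 0.65, rep(0.1, 60)), p = 100)
  emp <- snp_fdr(observed, null, mode = "empirical")
  # z = 0.6: i = 2 observed >= 0.6, n = 40 null >= 0.6 -> 40/(2*100)
  expect_equal(emp$i, c(1L, 2L))
  expect_equal(emp$n_null, c(0L, 40L))
  expect_equal(emp$fdr, c(0, 0.2))      # top SNP: n = 0 -> FDR 0
  lit <- snp_fdr(observed, null, mode = "as_printed")
  expect_equal(lit$fdr, c(Inf, 5.0))    # i*p/n = 2*100/40
})

test_that("FDR with exhaustive ties caps at 1, matching brute force", {
  observed <- c(0.4, 0.6)
  null <- make_null(rep(c(0.4, 0.6), 2), p = 2)
  emp <- snp_fdr(observed, null, mode = "empirical")
  expect_equal(emp$fdr, c(1, 1))
  expect_equal(emp$fdr, brute_fdr(observed, null$snp_null, 2))
})

test_that("empirical FDR matches the brute-force oracle on random scores", {
  set.seed(77)
  for (rep in 1:5) {
    observed <- round(runif(50), 2)     # rounding forces ties
    null_values <- round(runif(500), 2)
    p <- 10
    null <- make_null(null_values, p = p)
    emp <- snp_fdr(observed, null, mode = "empirical")
    expect_equal(emp$fdr, brute_fdr(observed, null_values, p))
    lit <- snp_fdr(observed, null, mode = "as_printed")
    expect_equal(lit$fdr, brute_fdr(observed, null_values, p, "as_printed"))
  }
})

test_that("empirical FDR decreases along the scan's sorted scores", {
  # with a dense null (p = 100 permutations of the same SNP set) the
  # null exceedance count shrinks in step with the observed one, so the
  # raw n/(i*p) estimator comes out monotone along the ranking
  sim <- simulate_pools(sim_config(n_genes = 40, snps_per_gene = 8,
                                   seed = 61))
  res <- run_scan(sim$records, sim$env, sim$design, scan_config(p = 100))
  fdr_sorted <- res$snp_table$fdr[order(res$snp_table$z)]
  # exactly monotone away from the cap; at the bottom of the ranking,
  # where FDR ~ 1, sampling noise of order 1/sqrt(n) can nudge it
  expect_true(all(diff(fdr_sorted) <= 0.01))
  strict <- fdr_sorted < 0.9
  expect_true(all(diff(fdr_sorted[strict]) <= 1e-12))
})

test_that("gene scores are mean Z over genes with enough scored SNPs", {
  genes <- c(rep("gA", 5), rep("gB", 4), rep("gC", 5))
  z <- c(0.2, 0.4, 0.6, 0.8, 1.0, rep(0.5, 4), rep(0.3, 5))
  gs <- gene_scores(genes, z, min_snps = 5)
  expect_equal(gs$gene, c("gA", "gC"))  # gB has only 4 scored SNPs
  expect_equal(gs$mean_z[gs$gene == "gA"], 0.6)
  expect_equal(gs$mean_z[gs$gene == "gC"], 0.3)   # constant z -> that z
  # NA (unscored) SNPs do not count toward membership
  z[1] <- NA
  gs2 <- gene_scores(genes, z, min_snps = 5)
  expect_false("gA" %in% gs2$gene)
})

test_that("gene-level FDR mirrors the SNP rule", {
  g1 <- data.frame(gene = "gA", n_snps = 5L, mean_z = 0.7)
  null <- make_null(numeric(0), p = 1, gene_null = 0.2, genes = "gA")
  expect_equal(gene_fdr(g1, null)$fdr, 0)
  g2 <- data.frame(gene = c("gA", "gB"), n_snps = c(5L, 6L),
                   mean_z = c(0.9, 0.3))
  null2 <- make_null(numeric(0), p = 10,
                     gene_null = c(rep(0.35, 12), rep(0.1, 8)),
                     genes = c("gA", "gB"))
  out <- gene_fdr(g2, null2)
  expect_equal(out$fdr[out$gene == "gB"], 12 / (2 * 10))
})

test_that("rerunning the scan with one seed reproduces every FDR", {
  sim <- simulate_pools(sim_config(n_genes = 15, snps_per_gene = 6,
                                   seed = 52))
  cfg <- scan_config(p = 15, seed = 8372)
  r1 <- run_scan(sim$records, sim$env, sim$design, cfg)
  r2 <- run_scan(sim$records, sim$env, sim$design, cfg)
  expect_identical(r1$snp_table, r2$snp_table)
  expect_identical(r1$gene_table, r2$gene_table)
  expect_identical(r1$null$snp_null, r2$null$snp_null)
})
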