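#' Generate permuted environment vectors
#'
#' Uniformly random permutations of the pool-to-value assignment, seeded
#' for reproducibility. Duplicate arrangements (and the identity) are
#' permitted — for a tied 3x3x3 temperature design only 1,680 distinct
#' arrangements exist, so collisions are expected at p = 100.
#'
#' @param env An \code{environment_vector} or numeric vector.
#' @param p Number of permutations (>= 1).
#' @param seed Integer RNG seed (default 8372).
#' @return A p x S matrix; each row is a permutation of the input values.
#' @export
permute_environment <- function(env, p, seed = 8372L) {
  ev <- if (inherits(env, "environment_vector")) env$values else env
  if (p < 1L) stop("need at least one permutation", call. = FALSE)
  S <- length(ev)
  out <- matrix(NA_real_, p, S)
  withr_seed(seed, {
    for (i in seq_len(p)) out[i, ] <- ev[sample.int(S)]
  })
  out
}

# Evaluate expr under a seed, restoring any prior RNG state afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Build the permutation null distribution
#'
#' Re-scores every usable SNP (and every qualifying gene) under \code{p}
#' random permutations of the environment labels. Allele frequencies —
#' and hence the whitened vectors, the covariance matrix, and gene
#' membership — do not change when only labels move, so they are computed
#' once and held fixed; each permutation costs one set of rank
#' correlations.
#'
#' @param std A \code{standardized_freqs} over the analysis SNP set.
#' @param model A \code{covariance_model}.
#' @param env An \code{environment_vector}.
#' @param genes Gene (supertranscript) label per SNP, for the gene-level
#'   null; genes qualify with >= \code{min_snps} scored SNPs.
#' @param p Number of permutations (default 100).
#' @param seed Integer seed (default 8372).
#' @param min_snps Minimum scored SNPs for a gene to be scored (default 5).
#' @return A list of class \code{null_distribution}: \code{p},
#'   \code{seed}, \code{snp_null} (numeric vector, p x K' values),
#'   \code{gene_null} (numeric vector over qualifying genes),
#'   \code{genes} (qualifying gene labels), \code{n_scored_per_perm}.
#' @export
build_null <- function(std, model, env, genes, p = 100L, seed = 8372L,
                       min_snps = 5L) {
  y <- whiten_frequencies(std, model)
  row_ranks <- rank_rows(y)
  scored <- !is.na(row_ranks[, 1L])
  if (p * sum(scored) == 0L) {
    stop("permutation null is empty: no scorable SNPs or p = 0",
         call. = FALSE)
  }
  perms <- permute_environment(env, p, seed)
  gene_of_scored <- genes[scored]
  tab <- table(gene_of_scored)
  qual_genes <- names(tab)[tab >= min_snps]
  snp_null <- vector("list", p)
  gene_null <- vector("list", p)
  for (i in seq_len(p)) {
    z <- spearman_against(row_ranks, perms[i, ])
    zs <- z[scored]
    snp_null[[i]] <- zs
    if (length(qual_genes)) {
      gm <- tapply(zs, gene_of_scored, mean)[qual_genes]
      gene_null[[i]] <- as.numeric(gm)
    } else {
      gene_null[[i]] <- numeric(0)
    }
  }
  structure(list(p = p, seed = seed,
                 snp_null = unlist(snp_null),
                 gene_null = unlist(gene_null),
                 genes = qual_genes,
                 n_scored_per_perm = sum(scored)),
            class = "null_distribution")
}

# Shared exceedance-counting core for SNP- and gene-level empirical FDR.
# For each observed score z: i = #{observed >= z} (ties count, including
# itself), n = #{null >= z}. Modes:
#   empirical:  FDR = n / (i * p), capped at 1; n = 0 -> 0
#   as_printed: FDR = i * p / n;              n = 0 -> Inf
empirical_fdr <- function(observed, null_values, p,
                          mode = c("empirical", "as_printed")) {
  mode <- match.arg(mode)
  obs_sorted <- sort(observed)
  null_sorted <- sort(null_values)
  K <- length(observed)
  # exceedance counts via sorted lookup: #{v >= z} = N - #{v < z}
  i_cnt <- K - findInterval(observed, obs_sorted, left.open = TRUE)
  n_cnt <- length(null_sorted) -
    findInterval(observed, null_sorted, left.open = TRUE)
  fdr <- if (mode == "empirical") {
    pmin(1, ifelse(n_cnt == 0, 0, n_cnt / (i_cnt * p)))
  } else {
    ifelse(n_cnt == 0, Inf, i_cnt * p / n_cnt)
  }
  data.frame(i = i_cnt, n_null = n_cnt, fdr = fdr)
}

#' Per-SNP empirical false discovery rate
#'
#' For each SNP with score \eqn{z}: \eqn{i} counts observed SNPs with an
#' equal or greater score, \eqn{n} counts pooled null scores equal or
#' greater, and \eqn{p} is the number of permutations. The default
#' \code{empirical} mode returns \eqn{n/(ip)} — expected null exceedances
#' per permutation over observed exceedances — capped at 1, with
#' \eqn{n = 0 \Rightarrow 0}; \code{as_printed} mode returns the literal
#' \eqn{ip/n} (with \eqn{n = 0 \Rightarrow \infty}), which is the
#' reciprocal of the former.
#'
#' @param observed Numeric vector of observed Z scores (NA-free).
#' @param null A \code{null_distribution}.
#' @param mode \code{"empirical"} (default) or \code{"as_printed"}.
#' @return Data frame with columns \code{i}, \code{n_null}, \code{fdr},
#'   one row per observed SNP.
#' @export
snp_fdr <- function(observed, null, mode = c("empirical", "as_printed")) {
  empirical_fdr(observed, null$snp_null, null$p, mode)
}

#' Gene-level mean-Z scores
#'
#' Aggregates SNP scores to their gene (supertranscript) by the
#' arithmetic mean; only genes with at least \code{min_snps} scored SNPs
#' are scored.
#'
#' @param genes Gene label per SNP.
#' @param z Z score per SNP (NA = unscored).
#' @param min_snps Minimum scored SNPs per gene (default 5).
#' @return Data frame \code{gene}, \code{n_snps}, \code{mean_z}, sorted
#'   by gene label.
#' @export
gene_scores <- function(genes, z, min_snps = 5L) {
  ok <- !is.na(z)
  if (!any(ok)) {
    return(data.frame(gene = character(), n_snps = integer(),
                      mean_z = numeric(), stringsAsFactors = FALSE))
  }
  n <- tapply(z[ok], genes[ok], length)
  mz <- tapply(z[ok], genes[ok], mean)
  keep <- n >= min_snps
  data.frame(gene = names(n)[keep],
             n_snps = as.integer(n[keep]),
             mean_z = as.numeric(mz[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene empirical false discovery rate
#'
#' Mirror of [snp_fdr()] at gene level: \eqn{i} counts observed genes
#' with an equal or greater mean Z, \eqn{n} counts null gene scores equal
#' or greater (genes qualify by the same >= \code{min_snps} rule in every
#' permutation; membership cannot change under label permutation).
#'
#' @param observed_genes Data frame from [gene_scores()].
#' @param null A \code{null_distribution} with \code{gene_null} filled.
#' @param mode \code{"empirical"} (default) or \code{"as_printed"}.
#' @return \code{observed_genes} with columns \code{i}, \code{n_null},
#'   \code{fdr} appended.
#' @export
gene_fdr <- function(observed_genes, null,
                     mode = c("empirical", "as_printed")) {
  res <- empirical_fdr(observed_genes$mean_z, null$gene_null, null$p, mode)
  cbind(observed_genes, res)
}
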