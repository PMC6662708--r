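#' Standardize per-pool allele frequencies
#'
#' For each SNP, the per-pool sample MAFs \eqn{\hat p_s = m_s/t_s} are
#' centred on the effective-allele-weighted grand mean
#' \eqn{\bar p = \sum_s e_s \hat p_s / \sum_s e_s} and scaled by the
#' binomial standard deviation at \eqn{\bar p}:
#' \deqn{x_s = (\hat p_s - \bar p) / \sqrt{\bar p (1 - \bar p)}.}
#' These standardized deviations are the raw material for both the
#' among-pool covariance matrix and the association score. SNPs whose
#' grand mean is exactly 0 or 1 carry no frequency information and are
#' flagged unusable.
#'
#' @param snps A \code{biallelic_snps} object. Analysis-filtered SNPs
#'   always qualify; SNPs with a zero-coverage pool (possible in the
#'   matrix set, whose filter tolerates up to three thin pools) have no
#'   defined frequency there and are flagged unusable.
#' @param design A \code{pool_design}.
#' @return A list of class \code{standardized_freqs}:
#'   \code{x} (K x S matrix, rows of unusable SNPs NA), \code{p_hat}
#'   (K x S), \code{p_bar} (length K), \code{usable} (logical K).
#' @export
standardize_frequencies <- function(snps, design) {
  K <- n_snps(snps)
  S <- n_pools(design)
  covered <- rowSums(snps$t < 1L) == 0L
  t_safe <- pmax(snps$t, 1L)
  nch <- matrix(design$n_chrom, K, S, byrow = TRUE)
  e <- effective_allele_number(nch, t_safe)
  p_hat <- snps$m / t_safe
  p_bar <- rowSums(e * p_hat) / rowSums(e)
  usable <- covered & p_bar > 0 & p_bar < 1
  p_hat[!covered, ] <- NA_real_
  p_bar[!covered] <- NA_real_
  x <- (p_hat - p_bar) / sqrt(p_bar * (1 - p_bar))
  x[!usable, ] <- NA_real_
  structure(list(x = x, p_hat = p_hat, p_bar = p_bar, usable = usable),
            class = "standardized_freqs")
}

#' Estimate the among-pool covariance of standardized frequencies
#'
#' The empirical covariance over the matrix-SNP set,
#' \eqn{\Omega = L^{-1} \sum_l x^{(l)} x^{(l)\top}}, captures shared
#' structure among pools (relatedness, shared drift, batch) that would
#' otherwise inflate association scores. Because \eqn{\Omega} from a
#' finite SNP set can be near-singular for 9 pools, a shrunk copy
#' \deqn{\Omega' = (1-\lambda)\Omega + \lambda\,\mathrm{diag}(\Omega)
#'   + \epsilon I, \quad \epsilon = 10^{-8}\,\mathrm{tr}(\Omega)/S}
#' is factorized for whitening; \eqn{\Omega} itself is returned unshrunk.
#'
#' @param std A \code{standardized_freqs} over the matrix SNP set.
#' @param lambda Shrinkage weight toward the diagonal, in \[0, 1\]
#'   (default 0.05).
#' @return A list of class \code{covariance_model}: \code{omega},
#'   \code{omega_shrunk}, \code{chol_lower} (lower-triangular factor with
#'   \code{omega_shrunk = chol_lower \%*\% t(chol_lower)}),
#'   \code{lambda}, \code{n_snps_used}.
#' @export
estimate_covariance <- function(std, lambda = 0.05) {
  x <- std$x[std$usable, , drop = FALSE]
  L <- nrow(x)
  if (L == 0L) {
    stop("no usable SNPs to estimate the covariance matrix", call. = FALSE)
  }
  S <- ncol(x)
  if (L < S) {
    warning(sprintf(
      "covariance estimated from only %d SNPs for %d pools; consider more matrix SNPs",
      L, S), call. = FALSE)
  }
  omega <- crossprod(x) / L
  omega <- (omega + t(omega)) / 2          # enforce exact symmetry
  eps <- 1e-8 * sum(diag(omega)) / S
  omega_shrunk <- (1 - lambda) * omega + lambda * diag(diag(omega), S) +
    diag(eps, S)
  ch <- tryCatch(chol(omega_shrunk), error = function(e) NULL)
  if (is.null(ch)) {
    stop("shrunk covariance matrix is not positive definite; ",
         "increase lambda", call. = FALSE)
  }
  structure(list(omega = omega, omega_shrunk = omega_shrunk,
                 chol_lower = t(ch), lambda = lambda, n_snps_used = L),
            class = "covariance_model")
}

#' Write a covariance matrix as a plain tab-separated file
#'
#' @param model A \code{covariance_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_covariance <- function(model, path) {
  utils::write.table(format(model$omega, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Whiten standardized frequencies by the covariance factor
#'
#' Solves \eqn{C y = x} for each SNP, where \eqn{C} is the
#' lower-triangular factor of the shrunk covariance, so that under the
#' null the components of \eqn{y} are decorrelated across pools.
#'
#' @param std A \code{standardized_freqs}.
#' @param model A \code{covariance_model}.
#' @return K x S matrix of whitened vectors (NA rows for unusable SNPs).
#' @export
whiten_frequencies <- function(std, model) {
  y <- matrix(NA_real_, nrow(std$x), ncol(std$x))
  ok <- std$usable
  if (any(ok)) {
    y[ok, ] <- t(forwardsolve(model$chol_lower, t(std$x[ok, , drop = FALSE])))
  }
  y
}

#' Score SNPs against the environment
#'
#' Each usable SNP's whitened frequency vector is compared with the
#' standardized environment by the absolute Spearman rank correlation
#' (average ranks for ties):
#' \deqn{Z = |\rho_{Spearman}(y, env)| \in [0, 1].}
#' The score is invariant to swapping major/minor labels (the sign of
#' \eqn{x}, hence of \eqn{y}, flips but \eqn{|\rho|} does not). SNPs whose
#' whitened vector is rank-constant have no defined score and get NA.
#'
#' @param std A \code{standardized_freqs} over the analysis SNP set.
#' @param model A \code{covariance_model}.
#' @param env An \code{environment_vector} (or numeric vector).
#' @return Numeric vector of Z scores in \[0, 1\], NA where undefined.
#' @export
z_scores <- function(std, model, env) {
  ev <- if (inherits(env, "environment_vector")) env$values else env
  y <- whiten_frequencies(std, model)
  z_scores_from_whitened(y, ev)
}

# Core scorer used for both the observed scan and the permutation null:
# the whitened matrix never changes under label permutation, only env does.
z_scores_from_whitened <- function(y, env_values) {
  ranks <- rank_rows(y)
  spearman_against(ranks, env_values)
}

# Average ranks per row; rows with any NA or zero spread come back NA.
rank_rows <- function(y) {
  r <- t(apply(y, 1L, function(v) {
    if (anyNA(v)) return(rep(NA_real_, length(v)))
    rank(v, ties.method = "average")
  }))
  if (nrow(y) == 1L) r <- matrix(r, nrow = 1L)
  spread <- apply(r, 1L, function(v) if (anyNA(v)) 0 else stats::sd(v))
  r[spread == 0, ] <- NA_real_
  r
}

# Pearson correlation of precomputed row ranks with the ranks of env:
# the tie-corrected Spearman statistic, vectorized over SNPs.
spearman_against <- function(row_ranks, env_values) {
  re <- rank(env_values, ties.method = "average")
  if (stats::sd(re) == 0) {
    stop("environment vector is constant; rank correlation undefined",
         call. = FALSE)
  }
  ok <- !is.na(row_ranks[, 1L])
  z <- rep(NA_real_, nrow(row_ranks))
  if (any(ok)) {
    z[ok] <- abs(as.vector(stats::cor(t(row_ranks[ok, , drop = FALSE]),
                                      re)))
  }
  z
}
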