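#' Reduce sync records to biallelic SNPs
#'
#' For each site, nucleotide counts (A, T, C, G; N and deletion columns are
#' never counted as alleles) are summed across pools. The two nucleotides
#' with the largest totals define the major and minor allele; ties are
#' broken by the fixed precedence A < T < C < G (sync column order), so the
#' reduction is deterministic and independent of record order. Per pool,
#' \code{m} is the minor-allele read count and \code{t} the coverage over
#' the two called alleles only — reads supporting a third allele at a
#' multi-allelic site are excluded from \code{t}. Sites where fewer than
#' two nucleotides have nonzero totals (monomorphic) are dropped.
#'
#' @param records A \code{sync_records} object.
#' @param design A \code{pool_design}.
#' @param drop_multiallelic Drop sites where a third nucleotide has any
#'   reads, instead of reducing them to their top two alleles.
#' @return An object of class \code{biallelic_snps}: list with
#'   \describe{
#'     \item{meta}{data frame \code{contig}, \code{pos}, \code{gene}
#'       (= contig, the supertranscript), \code{major}, \code{minor};}
#'     \item{m}{K x S integer matrix of minor-allele read counts;}
#'     \item{t}{K x S integer matrix of two-allele coverage.}
#'   }
#' @export
call_biallelic_snps <- function(records, design, drop_multiallelic = FALSE) {
  S <- n_pools(design)
  K <- nrow(records$meta)
  nuc <- records$counts[, , 1:4, drop = FALSE]          # A, T, C, G
  if (K == 0L) {
    return(biallelic_snps(
      data.frame(contig = character(), pos = integer(), gene = character(),
                 major = character(), minor = character(),
                 stringsAsFactors = FALSE),
      matrix(0L, 0L, S), matrix(0L, 0L, S)))
  }
  totals <- apply(nuc, c(1L, 3L), sum)                  # K x 4
  dim(totals) <- c(K, 4L)
  n_nonzero <- rowSums(totals > 0L)
  # order() is stable, so equal totals resolve by column order A < T < C < G
  ord <- apply(totals, 1L, function(v) order(v, decreasing = TRUE))  # 4 x K
  major_idx <- ord[1L, ]
  minor_idx <- ord[2L, ]
  keep <- n_nonzero >= 2L
  if (drop_multiallelic) keep <- keep & n_nonzero == 2L
  idx <- which(keep)
  m <- matrix(0L, length(idx), S)
  t <- matrix(0L, length(idx), S)
  for (j in seq_along(idx)) {
    k <- idx[j]
    m[j, ] <- nuc[k, , minor_idx[k]]
    t[j, ] <- nuc[k, , major_idx[k]] + m[j, ]
  }
  nuc_names <- c("A", "T", "C", "G")
  biallelic_snps(
    data.frame(contig = records$meta$contig[idx],
               pos = records$meta$pos[idx],
               gene = records$meta$contig[idx],
               major = nuc_names[major_idx[idx]],
               minor = nuc_names[minor_idx[idx]],
               stringsAsFactors = FALSE),
    m, t)
}

biallelic_snps <- function(meta, m, t) {
  structure(list(meta = meta, m = m, t = t), class = "biallelic_snps")
}

#' @export
print.biallelic_snps <- function(x, ...) {
  cat(sprintf("<biallelic_snps: %d SNPs x %d pools, %d gene(s)>\n",
              nrow(x$meta), ncol(x$m), length(unique(x$meta$gene))))
  invisible(x)
}

#' Subset a biallelic SNP set by row index
#'
#' @param snps A \code{biallelic_snps} object.
#' @param i Integer or logical index over SNP rows.
#' @return The subsetted \code{biallelic_snps}.
#' @export
subset_snps <- function(snps, i) {
  biallelic_snps(snps$meta[i, , drop = FALSE],
                 snps$m[i, , drop = FALSE],
                 snps$t[i, , drop = FALSE])
}

n_snps <- function(snps) nrow(snps$meta)

#' Effective allele number of a pooled sample
#'
#' The equivalent number of independently sampled chromosomes when
#' \code{c} reads are drawn from a pool of \code{n} chromosomes:
#' \deqn{e = (nc - 1) / (n + c).}
#' It combines the two finite-sampling stages harmonically: \eqn{e}
#' approaches \eqn{n} as coverage grows and approaches \eqn{c} when the
#' pool is large, so weighting by \eqn{e} down-weights samples whose
#' frequency estimate is noisier.
#'
#' @param n Chromosomes per pool (2 x diploid individuals), >= 1.
#' @param c Read coverage, >= 1. Vectorized over both arguments.
#' @return The effective allele number (dimensionless).
#' @export
effective_allele_number <- function(n, c) {
  if (any(c < 1) || any(n < 1)) {
    stop("effective allele number requires n >= 1 and coverage c >= 1",
         call. = FALSE)
  }
  (n * c - 1) / (n + c)
}

#' Per-sample minor allele frequency
#'
#' \code{MAF = m/t}: minor-supporting reads over total reads covering the
#' site (the two called alleles).
#'
#' @param m Minor-allele read count(s).
#' @param t Total read count(s), >= 1.
#' @return \code{m/t}, in \[0, 1\]. Vectorized.
#' @export
sample_maf <- function(m, t) {
  if (any(t < 1)) stop("sample MAF undefined at zero coverage", call. = FALSE)
  if (any(m < 0) || any(m > t)) {
    stop("minor count m must satisfy 0 <= m <= t", call. = FALSE)
  }
  m / t
}

#' Group minor allele frequency, weighted by effective allele number
#'
#' The group (treatment) MAF is the average of its pools' sample MAFs
#' weighted by each pool's effective allele number, so deeper-covered
#' pools — whose \eqn{m/t} carries less sampling error — count more:
#' \deqn{\bar p_g = \sum_{s \in g} e_s (m_s/t_s) / \sum_{s \in g} e_s.}
#'
#' @param m Minor-allele counts for the group's pools.
#' @param t Coverages for the group's pools (all >= 1).
#' @param n_chrom Chromosomes per pool (scalar or per-pool vector).
#' @return The weighted group MAF, a convex combination of sample MAFs.
#' @export
group_maf <- function(m, t, n_chrom) {
  if (length(m) != length(t)) stop("m and t lengths differ", call. = FALSE)
  if (any(t < 1)) {
    stop("group MAF requires coverage >= 1 in every contributing pool",
         call. = FALSE)
  }
  e <- effective_allele_number(rep(n_chrom, length.out = length(t)), t)
  weighted_maf(m / t, e)
}

#' Effective-allele-weighted average of sample MAFs
#'
#' The weighted-mean core of [group_maf()], usable directly when the
#' effective allele numbers are already in hand:
#' \eqn{\sum_s e_s \mathrm{MAF}_s / \sum_s e_s}.
#'
#' @param maf Per-pool sample MAFs.
#' @param e Per-pool effective allele numbers (positive weights).
#' @return The weighted mean frequency.
#' @export
weighted_maf <- function(maf, e) {
  if (length(maf) != length(e)) stop("maf and e lengths differ", call. = FALSE)
  if (any(e <= 0)) stop("effective allele numbers must be positive",
                        call. = FALSE)
  sum(e * maf) / sum(e)
}

#' Select the covariance-matrix SNP set
#'
#' Keeps SNPs covered by at least \code{min_cov} reads in at least
#' \code{min_samples} pools and whose minor allele is supported by at
#' least \code{min_minor_total} reads summed over all pools; then retains
#' exactly one SNP per transcript (the lowest-position qualifying SNP), so
#' the covariance estimate is not driven by linked sites within a gene.
#'
#' @param snps A \code{biallelic_snps} object.
#' @param min_cov Minimum per-pool coverage (default 5).
#' @param min_samples Minimum number of pools reaching \code{min_cov}
#'   (default 6).
#' @param min_minor_total Minimum total minor-allele reads (default 5).
#' @return The filtered \code{biallelic_snps}, one SNP per contig.
#' @export
filter_matrix_snps <- function(snps, min_cov = 5L, min_samples = 6L,
                               min_minor_total = 5L) {
  ok <- rowSums(snps$t >= min_cov) >= min_samples &
    rowSums(snps$m) >= min_minor_total
  kept <- subset_snps(snps, ok)
  if (n_snps(kept) == 0L) return(kept)
  ord <- order(kept$meta$contig, kept$meta$pos)
  first <- ord[!duplicated(kept$meta$contig[ord])]
  subset_snps(kept, sort(first))
}

#' Select the analysis SNP set
#'
#' Keeps SNPs covered by at least \code{min_cov} reads in \emph{every}
#' pool and whose minor allele is supported by at least
#' \code{min_minor_total} reads in total across pools. These are the SNPs
#' scored for association; the stricter coverage rule removes sites whose
#' frequency estimates are dominated by sampling error.
#'
#' @param snps A \code{biallelic_snps} object.
#' @param min_cov Minimum coverage required in every pool (default 5).
#' @param min_minor_total Minimum total minor-allele reads (default 15).
#' @return The filtered \code{biallelic_snps}.
#' @export
filter_analysis_snps <- function(snps, min_cov = 5L, min_minor_total = 15L) {
  ok <- rowSums(snps$t >= min_cov) == ncol(snps$t) &
    rowSums(snps$m) >= min_minor_total
  subset_snps(snps, ok)
}
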