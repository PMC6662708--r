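#' Simulation configuration for synthetic pooled sequencing
#'
#' Collects every generative parameter for [simulate_pools()]. The
#' defaults describe the study design the pipeline assumes: nine pools in
#' three temperature treatments (0, +1, +2 degC) of three replicates
#' each, four diploid individuals per pool, 200 genes of 10 SNPs, mean
#' read depth 50x.
#'
#' Per SNP \eqn{l} on gene \eqn{g} and pool \eqn{s} at temperature
#' \eqn{T_s}, the true minor-allele frequency is
#' \deqn{p_{l,s} = \mathrm{clamp}(\pi_l + \beta_g T_s + \gamma_{l,g(s)}
#'   + \delta_{l,s},\ 0,\ 1)}
#' with base frequency \eqn{\pi_l} from a Beta(\code{base_freq_shape1},
#' \code{base_freq_shape2}) truncated to \[0.05, 0.95\], effect
#' \eqn{\beta_g = \beta} for planted genes and 0 otherwise,
#' treatment-shared deviation \eqn{\gamma \sim N(0, \sigma_{group}^2)}
#' and pool deviation \eqn{\delta \sim N(0, \sigma_{pool}^2)}. The pool's
#' finite chromosome sample is \eqn{k \sim Binom(n_{chrom}, p)}, coverage
#' \eqn{c \sim \max(1, Pois(coverage\_mean))}, and minor reads
#' \eqn{m \sim Binom(c, (k/n)(1-\epsilon) + (1-k/n)\epsilon)} with
#' sequencing error \eqn{\epsilon}. This two-stage chain (pool then
#' reads) is exactly the error structure the effective allele number
#' \eqn{e = (nc-1)/(n+c)} summarizes.
#'
#' @param seed Integer RNG seed (default 8372).
#' @param design A \code{pool_design} (default [default_pool_design()]).
#' @param n_genes Number of genes/supertranscripts (default 200).
#' @param snps_per_gene SNPs per gene; scalar or length-2 range sampled
#'   uniformly per gene (default 10).
#' @param planted_fraction Fraction of genes with a temperature effect
#'   (default 0: global null).
#' @param beta Allele-frequency shift per degC for planted genes
#'   (default 0.15).
#' @param base_freq_shape1,base_freq_shape2 Beta parameters for the base
#'   minor-allele frequency, truncated to \[0.05, 0.95\] (defaults 1.5, 6).
#' @param sigma_group SD of the treatment-shared frequency deviation
#'   (default 0.02).
#' @param sigma_pool SD of the independent per-pool deviation
#'   (default 0.05).
#' @param coverage_mean Mean Poisson read depth, truncated at 1
#'   (default 50).
#' @param seq_error Per-read allele flip probability (default 0.001).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 8372L,
                       design = default_pool_design(),
                       n_genes = 200L,
                       snps_per_gene = 10L,
                       planted_fraction = 0,
                       beta = 0.15,
                       base_freq_shape1 = 1.5,
                       base_freq_shape2 = 6,
                       sigma_group = 0.02,
                       sigma_pool = 0.05,
                       coverage_mean = 50,
                       seq_error = 0.001) {
  stopifnot(planted_fraction >= 0, planted_fraction <= 1,
            coverage_mean >= 1, seq_error >= 0, seq_error <= 0.5,
            n_genes >= 1, all(snps_per_gene >= 1),
            beta >= -1, beta <= 1, sigma_group >= 0, sigma_pool >= 0,
            base_freq_shape1 > 0, base_freq_shape2 > 0)
  structure(list(seed = as.integer(seed), design = design,
                 n_genes = as.integer(n_genes),
                 snps_per_gene = as.integer(snps_per_gene),
                 planted_fraction = planted_fraction, beta = beta,
                 base_freq_shape1 = base_freq_shape1,
                 base_freq_shape2 = base_freq_shape2,
                 sigma_group = sigma_group, sigma_pool = sigma_pool,
                 coverage_mean = coverage_mean, seq_error = seq_error),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys error.
#' The design is given inline as parallel lists (\code{pool_id},
#' \code{treatment}, \code{temperature}, \code{n_ind}) under
#' \code{design}, or omitted for the default nine-pool layout.
#'
#' @param path Path to a YAML config.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$design)) {
    d <- raw$design
    raw$design <- pool_design(d$pool_id, d$treatment, d$temperature, d$n_ind)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown simulation config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' Simulate a pooled-sequencing dataset
#'
#' Draws a synthetic dataset under the generative model described in
#' [sim_config()] and returns it in the same containers the readers
#' produce, plus a truth table recording every latent quantity. The minor
#' allele is always written as C and the major as A, at consecutive
#' positions on one contig per gene, so downstream biallelic calling is
#' unambiguous.
#'
#' @param config A \code{sim_config}.
#' @return A list with \code{records} (\code{sync_records}), \code{env}
#'   (\code{environment_vector}, standardized from the design's raw
#'   temperatures), \code{design} (\code{pool_design}), and \code{truth}
#'   (data frame: gene, pos, planted, beta, pi, then per-pool true
#'   frequency \code{p_<pool>}, chromosome draw \code{k_<pool>}, coverage
#'   \code{c_<pool>}, minor reads \code{m_<pool>}).
#' @export
simulate_pools <- function(config) {
  design <- config$design
  S <- n_pools(design)
  withr_seed(config$seed, {
    G <- config$n_genes
    spg <- if (length(config$snps_per_gene) == 2L) {
      sample(config$snps_per_gene[1L]:config$snps_per_gene[2L], G,
             replace = TRUE)
    } else rep(config$snps_per_gene, G)
    K <- sum(spg)
    gene_names <- sprintf("gene%04d", seq_len(G))
    gene_of <- rep(seq_len(G), spg)
    pos <- sequence(spg)

    n_planted <- round(config$planted_fraction * G)
    planted <- c(rep(TRUE, n_planted), rep(FALSE, G - n_planted))[
      sample.int(G)]
    beta_gene <- ifelse(planted, config$beta, 0)

    pi <- stats::qbeta(
      stats::runif(K,
                   stats::pbeta(0.05, config$base_freq_shape1,
                                config$base_freq_shape2),
                   stats::pbeta(0.95, config$base_freq_shape1,
                                config$base_freq_shape2)),
      config$base_freq_shape1, config$base_freq_shape2)

    temp <- matrix(design$temperature, K, S, byrow = TRUE)
    treat_idx <- as.integer(factor(design$treatment,
                                   levels = unique(design$treatment)))
    n_treat <- max(treat_idx)
    gamma_tr <- matrix(stats::rnorm(K * n_treat, 0, config$sigma_group),
                       K, n_treat)
    gamma <- gamma_tr[, treat_idx, drop = FALSE]
    delta <- matrix(stats::rnorm(K * S, 0, config$sigma_pool), K, S)

    p_true <- pmin(pmax(pi + beta_gene[gene_of] * temp + gamma + delta, 0), 1)

    nch <- matrix(design$n_chrom, K, S, byrow = TRUE)
    k <- matrix(stats::rbinom(K * S, size = as.vector(nch),
                              prob = as.vector(p_true)), K, S)
    cov <- matrix(pmax(1L, stats::rpois(K * S, config$coverage_mean)), K, S)
    pf <- k / nch
    read_p <- pf * (1 - config$seq_error) + (1 - pf) * config$seq_error
    m <- matrix(stats::rbinom(K * S, size = as.vector(cov),
                              prob = as.vector(read_p)), K, S)
  })

  counts <- array(0L, dim = c(K, S, 6L),
                  dimnames = list(NULL, design$pool_id, NUC_ORDER))
  counts[, , 1L] <- cov - m      # major allele written as A
  counts[, , 3L] <- m            # minor allele written as C
  records <- sync_records(
    data.frame(contig = gene_names[gene_of], pos = pos,
               ref = rep("A", K), stringsAsFactors = FALSE),
    counts)

  truth <- data.frame(gene = gene_names[gene_of], pos = pos,
                      planted = planted[gene_of],
                      beta = beta_gene[gene_of], pi = pi,
                      stringsAsFactors = FALSE)
  add_block <- function(mat, prefix) {
    cols <- as.data.frame(mat)
    names(cols) <- paste0(prefix, "_", design$pool_id)
    cols
  }
  truth <- cbind(truth, add_block(p_true, "p"), add_block(k, "k"),
                 add_block(cov, "c"), add_block(m, "m"))

  env <- environment_vector(design$temperature, design, standardize = TRUE)
  list(records = records, env = env, design = design, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the four artifacts of one simulated study: sync file,
#' raw-temperature environment file, pool-design TSV, truth-table TSV.
#'
#' @param sim Result of [simulate_pools()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sync = file.path(dir, "pools.sync"),
             env = file.path(dir, "temperatures.txt"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_sync(sim$records, paths[["sync"]])
  write_environment(sim$env, paths[["env"]], raw = TRUE)
  write_design(sim$design, paths[["design"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
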