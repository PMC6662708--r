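#' Scan configuration
#'
#' All thresholds and knobs of the end-to-end scan, with the pipeline's
#' defaults: coverage filters at 5 reads, matrix SNPs in >= 6 pools with
#' >= 5 total minor reads, analysis SNPs covered in every pool with >= 15
#' total minor reads, genes scored at >= 5 SNPs, 100 permutations, seed
#' 8372, diagonal shrinkage 0.05, empirical FDR, report threshold
#' Z > 0.49998.
#'
#' @param min_cov Minimum per-pool coverage for both filters (default 5).
#' @param min_samples_matrix Pools that must reach \code{min_cov} for the
#'   matrix set (default 6).
#' @param min_minor_matrix Minimum total minor reads, matrix set
#'   (default 5).
#' @param min_minor_analysis Minimum total minor reads, analysis set
#'   (default 15).
#' @param min_snps_per_gene Minimum scored SNPs per gene (default 5).
#' @param p Number of label permutations (default 100).
#' @param seed Integer RNG seed (default 8372).
#' @param lambda Covariance shrinkage (default 0.05).
#' @param fdr_formula \code{"empirical"} or \code{"as_printed"}.
#' @param z_report_threshold Z cutoff reported in the summary
#'   (default 0.49998); a reporting device, not an inference step.
#' @param disjoint_matrix Exclude matrix SNPs from the analysis set
#'   (default FALSE).
#' @param drop_multiallelic Drop (rather than reduce) sites with a third
#'   allele (default FALSE).
#' @return A list of class \code{scan_config}.
#' @export
scan_config <- function(min_cov = 5L, min_samples_matrix = 6L,
                        min_minor_matrix = 5L, min_minor_analysis = 15L,
                        min_snps_per_gene = 5L, p = 100L, seed = 8372L,
                        lambda = 0.05,
                        fdr_formula = c("empirical", "as_printed"),
                        z_report_threshold = 0.49998,
                        disjoint_matrix = FALSE,
                        drop_multiallelic = FALSE) {
  fdr_formula <- match.arg(fdr_formula)
  stopifnot(min_cov >= 1, min_samples_matrix >= 1, min_minor_matrix >= 0,
            min_minor_analysis >= 0, min_snps_per_gene >= 1, p >= 1,
            lambda >= 0, lambda <= 1)
  structure(list(min_cov = as.integer(min_cov),
                 min_samples_matrix = as.integer(min_samples_matrix),
                 min_minor_matrix = as.integer(min_minor_matrix),
                 min_minor_analysis = as.integer(min_minor_analysis),
                 min_snps_per_gene = as.integer(min_snps_per_gene),
                 p = as.integer(p), seed = as.integer(seed),
                 lambda = lambda, fdr_formula = fdr_formula,
                 z_report_threshold = z_report_threshold,
                 disjoint_matrix = disjoint_matrix,
                 drop_multiallelic = drop_multiallelic),
            class = "scan_config")
}

#' Run the full association scan
#'
#' Orchestrates the pipeline: biallelic calling, matrix/analysis
#' filtering, covariance estimation, covariance-whitened Spearman Z
#' scoring against the environment, label-permutation null, and
#' empirical FDR at SNP and gene level. Inputs may be file paths or the
#' in-memory objects the readers return.
#'
#' @param sync A \code{sync_records} object or path to a sync file.
#' @param env An \code{environment_vector}, numeric vector, or path to an
#'   environment file.
#' @param design A \code{pool_design} or path to a design TSV.
#' @param config A \code{scan_config}.
#' @param standardize_env If \code{env} holds raw temperatures,
#'   standardize on read (default FALSE: file is pre-standardized).
#' @return A list of class \code{scan_result}:
#'   \describe{
#'     \item{snp_table}{per-SNP data frame: contig, pos, gene, major,
#'       minor, z, i, n_null, fdr;}
#'     \item{gene_table}{per-gene data frame: gene, n_snps, mean_z, i,
#'       n_null, fdr;}
#'     \item{summary}{named list of the headline counts;}
#'     \item{attrition}{per-stage SNP counts (input/kept per stage);}
#'     \item{model}{the \code{covariance_model};}
#'     \item{null}{the \code{null_distribution};}
#'     \item{config}{the \code{scan_config} used.}
#'   }
#' @export
run_scan <- function(sync, env, design, config = scan_config(),
                     standardize_env = FALSE) {
  if (is.character(design)) design <- read_design(design)
  if (is.character(sync)) sync <- read_sync(sync, design)
  if (is.character(env)) {
    env <- read_environment(env, design, standardize = standardize_env)
  } else if (!inherits(env, "environment_vector")) {
    env <- environment_vector(env, design, standardize = standardize_env)
  }

  snps <- call_biallelic_snps(sync, design,
                              drop_multiallelic = config$drop_multiallelic)
  matrix_set <- filter_matrix_snps(snps, config$min_cov,
                                   config$min_samples_matrix,
                                   config$min_minor_matrix)
  analysis_set <- filter_analysis_snps(snps, config$min_cov,
                                       config$min_minor_analysis)
  if (config$disjoint_matrix && n_snps(analysis_set) > 0L) {
    key <- function(s) paste(s$meta$contig, s$meta$pos)
    analysis_set <- subset_snps(analysis_set,
                                !(key(analysis_set) %in% key(matrix_set)))
  }

  attrition <- data.frame(
    stage = c("sync_sites", "biallelic", "matrix_set", "analysis_set"),
    n = c(nrow(sync$meta), n_snps(snps), n_snps(matrix_set),
          n_snps(analysis_set)),
    stringsAsFactors = FALSE)

  if (n_snps(analysis_set) == 0L || n_snps(matrix_set) == 0L) {
    warning("no SNPs survive filtering; returning an empty scan result",
            call. = FALSE)
    return(empty_scan_result(config, attrition))
  }

  std_matrix <- standardize_frequencies(matrix_set, design)
  model <- estimate_covariance(std_matrix, lambda = config$lambda)

  std <- standardize_frequencies(analysis_set, design)
  z <- z_scores(std, model, env)
  scored <- !is.na(z)
  n_unusable <- sum(!std$usable)
  n_undef <- sum(!scored) - n_unusable
  if (n_unusable > 0L || n_undef > 0L) {
    message(sprintf(
      "excluded from scoring: %d SNP(s) with degenerate mean frequency, %d with rank-constant whitened vector",
      n_unusable, n_undef))
  }

  null <- build_null(std, model, env, analysis_set$meta$gene,
                     p = config$p, seed = config$seed,
                     min_snps = config$min_snps_per_gene)

  obs_z <- z[scored]
  snp_fdr_tab <- snp_fdr(obs_z, null, mode = config$fdr_formula)
  snp_table <- cbind(
    analysis_set$meta[scored, c("contig", "pos", "gene", "major", "minor"),
                      drop = FALSE],
    data.frame(z = obs_z), snp_fdr_tab)
  rownames(snp_table) <- NULL

  genes_obs <- gene_scores(analysis_set$meta$gene, z,
                           min_snps = config$min_snps_per_gene)
  gene_table <- if (nrow(genes_obs)) {
    gene_fdr(genes_obs, null, mode = config$fdr_formula)
  } else {
    cbind(genes_obs, data.frame(i = integer(), n_null = integer(),
                                fdr = numeric()))
  }

  summary <- list(
    n_snps = nrow(snp_table),
    n_snps_above_z = sum(snp_table$z > config$z_report_threshold),
    n_snps_fdr05 = sum(snp_table$fdr <= 0.05),
    n_genes = nrow(gene_table),
    n_genes_fdr05 = if (nrow(gene_table)) sum(gene_table$fdr <= 0.05) else 0L,
    go_terms = "not computed",
    fdr_formula = config$fdr_formula,
    seed = config$seed,
    p = config$p,
    z_report_threshold = config$z_report_threshold)

  structure(list(snp_table = snp_table, gene_table = gene_table,
                 summary = summary, attrition = attrition, model = model,
                 null = null, config = config),
            class = "scan_result")
}

empty_scan_result <- function(config, attrition) {
  snp_table <- data.frame(contig = character(), pos = integer(),
                          gene = character(), major = character(),
                          minor = character(), z = numeric(),
                          i = integer(), n_null = integer(),
                          fdr = numeric(), stringsAsFactors = FALSE)
  gene_table <- data.frame(gene = character(), n_snps = integer(),
                           mean_z = numeric(), i = integer(),
                           n_null = integer(), fdr = numeric(),
                           stringsAsFactors = FALSE)
  structure(list(snp_table = snp_table, gene_table = gene_table,
                 summary = list(n_snps = 0L, n_snps_above_z = 0L,
                                n_snps_fdr05 = 0L, n_genes = 0L,
                                n_genes_fdr05 = 0L,
                                go_terms = "not computed",
                                fdr_formula = config$fdr_formula,
                                seed = config$seed, p = config$p,
                                z_report_threshold = config$z_report_threshold),
                 attrition = attrition, model = NULL, null = NULL,
                 config = config),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(format_summary(x), sep = "\n")
  invisible(x)
}

format_summary <- function(scan) {
  s <- scan$summary
  c("Association scan summary",
    sprintf("  Number of SNPs analysed: %d", s$n_snps),
    sprintf("  Number of SNPs with Z-score > %s: %d",
            format(s$z_report_threshold), s$n_snps_above_z),
    sprintf("  Number of SNPs with FDR <= 0.05: %d", s$n_snps_fdr05),
    sprintf("  Number of genes with >= %d SNPs: %d",
            scan$config$min_snps_per_gene, s$n_genes),
    sprintf("  Number of genes with FDR <= 0.05: %d", s$n_genes_fdr05),
    sprintf("  Number of GO terms with FDR <= 0.05: %s", s$go_terms),
    sprintf("  FDR formula: %s; permutations: %d; seed: %d",
            s$fdr_formula, s$p, s$seed))
}

#' Write scan results to a directory
#'
#' Writes the per-SNP table (\code{snps.tsv}), per-gene table
#' (\code{genes.tsv}), the plain-text summary block (\code{summary.txt}),
#' the per-stage attrition table (\code{attrition.tsv}), the covariance
#' matrix (\code{covariance.tsv}) and the serialized configuration
#' (\code{config.yaml}). Re-running on an identical scan result produces
#' byte-identical files.
#'
#' @param scan A \code{scan_result}.
#' @param out_dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_results <- function(scan, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  paths <- c(snps = file.path(out_dir, "snps.tsv"),
             genes = file.path(out_dir, "genes.tsv"),
             summary = file.path(out_dir, "summary.txt"),
             attrition = file.path(out_dir, "attrition.tsv"),
             config = file.path(out_dir, "config.yaml"))
  write_tsv <- function(df, path) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(v)
      format(v, digits = 15, scientific = FALSE, trim = TRUE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(scan$snp_table, paths[["snps"]])
  write_tsv(scan$gene_table, paths[["genes"]])
  writeLines(format_summary(scan), paths[["summary"]])
  write_tsv(scan$attrition, paths[["attrition"]])
  cfg <- unclass(scan$config)
  yaml::write_yaml(cfg, paths[["config"]])
  if (!is.null(scan$model)) {
    paths <- c(paths, covariance = file.path(out_dir, "covariance.tsv"))
    write_covariance(scan$model, paths[["covariance"]])
  }
  invisible(paths)
}
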