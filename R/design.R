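#' Construct a pool design table
#'
#' A pool design describes the pooled samples in the order their count
#' columns appear in the sync file: one row per pool with its treatment
#' label, the temperature it experienced, and the number of diploid
#' individuals pooled. The haploid chromosome count per pool
#' (\code{n_chrom = 2 * n_ind}) is derived and attached; it is the pool
#' size \eqn{n} entering the effective allele number
#' \eqn{e = (nc - 1)/(n + c)}.
#'
#' @param pool_id Character vector of unique pool labels.
#' @param treatment Character vector of treatment labels (e.g. "control",
#'   "plus1", "plus2"), one per pool.
#' @param temperature Numeric vector of temperatures in degrees Celsius.
#' @param n_ind Integer vector (or scalar, recycled) of diploid individuals
#'   per pool; must be >= 1.
#'
#' @return A data frame of class \code{pool_design} with columns
#'   \code{pool_id}, \code{treatment}, \code{temperature}, \code{n_ind},
#'   \code{n_chrom}.
#' @seealso [default_pool_design()] for the 9-pool heated-panel layout.
#' @export
pool_design <- function(pool_id, treatment, temperature, n_ind) {
  n_ind <- as.integer(rep(n_ind, length.out = length(pool_id)))
  if (anyDuplicated(pool_id)) {
    stop("pool_id values must be unique", call. = FALSE)
  }
  if (length(treatment) != length(pool_id) ||
      length(temperature) != length(pool_id)) {
    stop("treatment and temperature must have one entry per pool",
         call. = FALSE)
  }
  if (any(is.na(n_ind)) || any(n_ind < 1L)) {
    stop("n_ind must be an integer >= 1 for every pool", call. = FALSE)
  }
  out <- data.frame(
    pool_id = as.character(pool_id),
    treatment = as.character(treatment),
    temperature = as.numeric(temperature),
    n_ind = n_ind,
    n_chrom = 2L * n_ind,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pool_design", "data.frame")
  out
}

#' Default nine-pool design: three treatments, three replicates
#'
#' The layout the pipeline's defaults assume: nine pools in three
#' temperature treatments (ambient control, +1 degC, +2 degC) with three
#' replicate pools each and four diploid individuals per pool (eight
#' chromosomes).
#'
#' @param n_ind Diploid individuals per pool (default 4).
#' @return A \code{pool_design} with 9 rows.
#' @export
default_pool_design <- function(n_ind = 4L) {
  pool_design(
    pool_id = c("control_1", "control_2", "control_3",
                "plus1_1", "plus1_2", "plus1_3",
                "plus2_1", "plus2_2", "plus2_3"),
    treatment = rep(c("control", "plus1", "plus2"), each = 3L),
    temperature = rep(c(0, 1, 2), each = 3L),
    n_ind = n_ind
  )
}

#' Read a pool design from a tab-separated file
#'
#' Expects a header line \code{pool_id treatment temperature n_ind}
#' (tab-separated). Row order defines the sync column order.
#'
#' @param path Path to the design TSV.
#' @return A \code{pool_design}.
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("pool_id", "treatment", "temperature", "n_ind")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("design file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pool_design(df$pool_id, df$treatment, df$temperature, df$n_ind)
}

#' Write a pool design table
#'
#' @param design A \code{pool_design}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[, c("pool_id", "treatment", "temperature", "n_ind")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

n_pools <- function(design) nrow(design)
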