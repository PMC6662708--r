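NUC_ORDER <- c("A", "T", "C", "G", "N", "del")

#' Read a PoPoolation2 sync file
#'
#' Each data line is \code{contig<TAB>pos<TAB>ref<TAB>A:T:C:G:N:del ...}
#' with one colon-separated count sextuple per pool, in design order.
#' Contig names may contain any non-whitespace characters; positions are
#' 1-based (pileup convention).
#'
#' @param path Path to the sync file.
#' @param design A \code{pool_design}; its row count fixes the expected
#'   number of count columns.
#' @return An object of class \code{sync_records}: a list with
#'   \describe{
#'     \item{meta}{data frame \code{contig}, \code{pos}, \code{ref} in
#'       file order;}
#'     \item{counts}{integer array \code{[record, pool, nucleotide]} with
#'       the third dimension ordered A, T, C, G, N, del.}
#'   }
#' @export
read_sync <- function(path, design) {
  if (!file.exists(path)) stop("sync file not found: ", path, call. = FALSE)
  S <- n_pools(design)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("sync file '", path, "' contains no records", call. = FALSE)
    return(sync_records(
      data.frame(contig = character(), pos = integer(), ref = character(),
                 stringsAsFactors = FALSE),
      array(0L, dim = c(0L, S, 6L))
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 3L + S)
  if (length(bad)) {
    stop(sprintf(
      "sync line %d has %d columns; expected %d (contig, pos, ref + %d pools)",
      bad[1L], nf[bad[1L]], 3L + S, S), call. = FALSE)
  }
  K <- length(fields)
  mat <- matrix(unlist(fields), nrow = 3L + S)   # columns = records
  pos <- suppressWarnings(as.integer(mat[2L, ]))
  if (anyNA(pos)) {
    stop("sync line ", which(is.na(pos))[1L], ": non-integer position",
         call. = FALSE)
  }
  counts <- array(0L, dim = c(K, S, 6L),
                  dimnames = list(NULL, design$pool_id, NUC_ORDER))
  for (s in seq_len(S)) {
    parts <- strsplit(mat[3L + s, ], ":", fixed = TRUE)
    arity <- lengths(parts)
    if (any(arity != 6L)) {
      stop(sprintf(
        "sync line %d, pool %d: count field has %d entries; expected 6 (A:T:C:G:N:del)",
        which(arity != 6L)[1L], s, arity[arity != 6L][1L]), call. = FALSE)
    }
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v)) {
      bad_rec <- which(is.na(matrix(v, nrow = 6L)), arr.ind = TRUE)[1L, 2L]
      stop(sprintf("sync line %d, pool %d: non-integer allele count",
                   bad_rec, s), call. = FALSE)
    }
    counts[, s, ] <- matrix(v, ncol = 6L, byrow = TRUE)
  }
  sync_records(
    data.frame(contig = mat[1L, ], pos = pos, ref = mat[3L, ],
               stringsAsFactors = FALSE),
    counts
  )
}

sync_records <- function(meta, counts) {
  structure(list(meta = meta, counts = counts), class = "sync_records")
}

#' @export
print.sync_records <- function(x, ...) {
  cat(sprintf("<sync_records: %d sites x %d pools>\n",
              nrow(x$meta), dim(x$counts)[2L]))
  invisible(x)
}

#' Write sync records in canonical formatting
#'
#' The inverse of [read_sync()]: tab-separated columns, colon-separated
#' integer sextuples, no scientific notation. Round-trips byte-for-byte
#' through [read_sync()].
#'
#' @param records A \code{sync_records} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sync <- function(records, path) {
  K <- nrow(records$meta)
  S <- dim(records$counts)[2L]
  pool_cols <- vapply(seq_len(S), function(s) {
    cc <- format(records$counts[, s, , drop = FALSE], scientific = FALSE,
                 trim = TRUE)
    dim(cc) <- c(K, 6L)
    apply(cc, 1L, paste, collapse = ":")
  }, character(K))
  if (K == 1L) pool_cols <- matrix(pool_cols, nrow = 1L)
  lines <- do.call(paste, c(
    list(records$meta$contig, records$meta$pos, records$meta$ref),
    lapply(seq_len(S), function(s) pool_cols[, s]),
    sep = "\t"
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Read (and optionally standardize) the environment vector
#'
#' The environment file holds a single row of tab-separated numbers, one
#' per pool in design order. The file may contain either pre-standardized
#' values (the usual case; \code{standardize = FALSE} passes them through)
#' or raw temperatures in degrees Celsius with \code{standardize = TRUE},
#' in which case \eqn{(T - mean(T))/sd(T)} is applied.
#'
#' @param path Path to the environment file.
#' @param design A \code{pool_design}.
#' @param standardize Logical; z-score the values before returning?
#' @return An \code{environment_vector}: list with \code{values}
#'   (standardized) and \code{raw} (as read).
#' @export
read_environment <- function(path, design, standardize = FALSE) {
  row <- scan(path, what = numeric(), sep = "\t", quiet = TRUE)
  environment_vector(row, design, standardize = standardize)
}

#' Build an environment vector from numeric values
#'
#' @param values One value per pool, design order.
#' @param design A \code{pool_design}.
#' @param standardize Logical; apply \eqn{(x - mean)/sd}?
#' @return An \code{environment_vector}.
#' @export
environment_vector <- function(values, design, standardize = FALSE) {
  values <- as.numeric(values)
  if (length(values) != n_pools(design)) {
    stop(sprintf("environment vector has %d values but design has %d pools",
                 length(values), n_pools(design)), call. = FALSE)
  }
  raw <- values
  if (standardize) {
    s <- stats::sd(values)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize a constant environment vector (sd = 0)",
           call. = FALSE)
    }
    values <- (values - mean(values)) / s
  }
  structure(list(values = values, raw = raw),
            class = "environment_vector")
}

#' Write an environment vector as a one-row tab-separated file
#'
#' @param env An \code{environment_vector} or numeric vector.
#' @param path Output path.
#' @param raw Write the raw values instead of the standardized ones?
#' @return \code{path}, invisibly.
#' @export
write_environment <- function(env, path, raw = FALSE) {
  v <- if (inherits(env, "environment_vector")) {
    if (raw) env$raw else env$values
  } else as.numeric(env)
  writeLines(paste(format(v, scientific = FALSE, trim = TRUE, digits = 15),
                   collapse = "\t"), path)
  invisible(path)
}
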