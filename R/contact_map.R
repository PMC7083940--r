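#' Contact map container
#'
#' A symmetric, nonnegative, binned contact matrix plus the metadata needed
#' by downstream stages: bin size, per-bin validity mask, normalization
#' state and the circularity of the underlying genome.
#'
#' @param matrix square numeric matrix, symmetric and nonnegative.
#' @param bin_size_bp bin size in bp.
#' @param valid logical vector, one flag per bin; masked bins are zeroed.
#' @param normalized logical; `TRUE` after [scn_normalize()].
#' @param circular logical; circular genome (default `TRUE`).
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(matrix, bin_size_bp, valid = NULL, normalized = FALSE,
                        circular = TRUE) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    stop("`matrix` must be square", call. = FALSE)
  }
  if (max(abs(matrix - t(matrix))) > 1e-9 * max(1, max(abs(matrix)))) {
    stop("`matrix` must be symmetric", call. = FALSE)
  }
  if (any(matrix < 0)) stop("`matrix` must be nonnegative", call. = FALSE)
  n <- nrow(matrix)
  if (is.null(valid)) valid <- rep(TRUE, n)
  stopifnot(length(valid) == n)
  matrix[!valid, ] <- 0
  matrix[, !valid] <- 0
  dimnames(matrix) <- NULL
  structure(list(
    matrix = matrix,
    bin_size_bp = as.numeric(bin_size_bp),
    valid = as.logical(valid),
    normalized = isTRUE(normalized),
    circular = isTRUE(circular)
  ), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> %d x %d bins of %.0f bp, %d valid, %s%s\n",
    nrow(x$matrix), ncol(x$matrix), x$bin_size_bp, sum(x$valid),
    if (x$normalized) "SCN-normalized" else "raw counts",
    if (x$circular) ", circular" else ""
  ))
  invisible(x)
}

#' @export
dim.contact_map <- function(x) dim(x$matrix)

#' Rotate a contact map so a chosen bin sits at the matrix center
#'
#' Pure index roll on the circular genome; used for ori-centered display.
#'
#' @param map a `contact_map`.
#' @param center_bp genomic position to place at the central bin.
#' @return a rotated `contact_map`.
#' @export
rotate_map <- function(map, center_bp) {
  if (!map$circular) stop("rotation requires a circular genome", call. = FALSE)
  n <- nrow(map$matrix)
  c_bin <- as.integer(center_bp %/% map$bin_size_bp) %% n
  shift <- (c_bin - n %/% 2L) %% n
  idx <- ((seq_len(n) - 1L + shift) %% n) + 1L
  contact_map(map$matrix[idx, idx], map$bin_size_bp, map$valid[idx],
              normalized = map$normalized, circular = TRUE)
}

#' Write / read contact matrices as text
#'
#' Dense maps are tab-separated with no header; sparse maps are triplet
#' text `bin_i<TAB>bin_j<TAB>value` (0-based, upper triangle including the
#' diagonal).
#'
#' @param map a `contact_map` (or plain matrix for `write_dense_matrix`).
#' @param path output file.
#' @name map_io
NULL

#' @rdname map_io
#' @export
write_dense_matrix <- function(map, path) {
  m <- if (inherits(map, "contact_map")) map$matrix else map
  utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname map_io
#' @export
read_dense_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' @rdname map_io
#' @export
write_sparse_matrix <- function(map, path) {
  m <- if (inherits(map, "contact_map")) map$matrix else map
  keep <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  df <- data.frame(bin_i = keep[, 1] - 1L, bin_j = keep[, 2] - 1L,
                   value = m[keep])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname map_io
#' @param n_bins matrix dimension for sparse input.
#' @export
read_sparse_matrix <- function(path, n_bins) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  m <- matrix(0, n_bins, n_bins)
  m[cbind(df$bin_i + 1L, df$bin_j + 1L)] <- df$value
  m[cbind(df$bin_j + 1L, df$bin_i + 1L)] <- df$value
  m
}

#' @rdname map_io
#' @param valid logical mask to write as valid 0-based bin indices.
#' @export
write_valid_bins <- function(valid, path) {
  writeLines(as.character(which(valid) - 1L), path)
  invisible(path)
}

#' @rdname map_io
#' @export
read_valid_bins <- function(path, n_bins) {
  idx <- as.integer(readLines(path))
  v <- rep(FALSE, n_bins)
  v[idx + 1L] <- TRUE
  v
}
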