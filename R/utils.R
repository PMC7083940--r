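# Internal helpers shared across modules.

#' Circular distance between integer indices
#'
#' Distance on a circle of `n` positions: `min(|i - j|, n - |i - j|)`.
#' Inputs are recycled; indices may be any integers (reduced mod `n`).
#'
#' @param i,j integer vectors of positions (0-based or 1-based, consistently).
#' @param n circle size.
#' @return integer vector of distances in `[0, floor(n/2)]`.
#' @keywords internal
circ_dist <- function(i, j, n) {
  d <- abs(((i - j) %% n))
  pmin(d, n - d)
}

# Fold a signed offset onto (-n/2, n/2].
fold_circ <- function(x, n) {
  x <- x %% n
  ifelse(x > n / 2, x - n, x)
}

# Derive a sub-seed from a master seed; double arithmetic avoids integer
# overflow and the result stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483111) * 69069 +
                as.numeric(k) * 12347) %% 2147483111)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive scalar", name), call. = FALSE)
  }
  invisible(TRUE)
}
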