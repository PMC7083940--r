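# Sequential component normalization (SCN) of contact maps: alternating L1
# row/column scaling of the valid submatrix toward a doubly stochastic
# limit, equalizing per-bin visibility.

#' Mask poorly covered bins
#'
#' Bins with zero total coverage, or with total coverage below the given
#' quantile of the nonzero-bin coverages, are masked (symmetrically) before
#' normalization.
#'
#' @param raw_map a raw-count `contact_map`.
#' @param min_coverage_quantile quantile in `[0, 1)` of nonzero-bin
#'   coverages used as the cutoff (default 0.01).
#' @return logical validity mask, one flag per bin.
#' @export
filter_bins <- function(raw_map, min_coverage_quantile = 0.01) {
  stopifnot(inherits(raw_map, "contact_map"))
  if (min_coverage_quantile < 0 || min_coverage_quantile >= 1) {
    stop("min_coverage_quantile must be in [0, 1)", call. = FALSE)
  }
  cov <- rowSums(raw_map$matrix)
  valid <- cov > 0
  if (any(valid) && min_coverage_quantile > 0) {
    cutoff <- stats::quantile(cov[valid], min_coverage_quantile, names = FALSE)
    valid <- valid & cov >= cutoff
  }
  valid & raw_map$valid
}

#' Sequential component normalization
#'
#' Iteratively divides each valid row by its sum, then each valid column by
#' its sum, until every valid row sum is within `tol` of 1 or `max_iter`
#' passes are exhausted. The result is symmetrized as `(M + t(M)) / 2`,
#' removing the residual half-step asymmetry. Masked bins stay zero.
#' Non-convergence raises a warning and is flagged on the result, not an
#' error.
#'
#' @param raw_map a symmetric `contact_map` of raw counts.
#' @param valid logical mask from [filter_bins()]; defaults to the map's own
#'   mask combined with a zero-coverage filter.
#' @param tol convergence tolerance on `max |rowsum - 1|` (default 1e-6).
#' @param max_iter maximum alternating passes (default 200).
#' @return a normalized `contact_map` with attributes `iterations` and
#'   `converged`.
#' @export
scn_normalize <- function(raw_map, valid = NULL, tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(raw_map, "contact_map"))
  if (is.null(valid)) valid <- filter_bins(raw_map, 0)
  if (sum(valid) < 2L) stop("fewer than 2 valid bins", call. = FALSE)
  m <- raw_map$matrix[valid, valid, drop = FALSE]
  if (any(rowSums(m) == 0)) {
    stop("valid mask leaves zero-coverage bins; run filter_bins first",
         call. = FALSE)
  }
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    m <- m / rowSums(m)
    m <- t(t(m) / colSums(m))
    if (max(abs(rowSums(m) - 1)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("SCN did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  m <- (m + t(m)) / 2
  out <- matrix(0, nrow(raw_map$matrix), ncol(raw_map$matrix))
  out[valid, valid] <- m
  res <- contact_map(out, raw_map$bin_size_bp, valid, normalized = TRUE,
                     circular = raw_map$circular)
  attr(res, "iterations") <- iter
  attr(res, "converged") <- converged
  res
}

#' Clip a map for display
#'
#' Returns a clipped copy for plotting; the underlying data are unchanged.
#' By default the ceiling is the `q`-quantile of the positive entries
#' (`method = "quantile"`); `method = "fraction_of_max"` instead uses
#' `q * max(map)`, the literal reading of a saturation threshold at a
#' percentage of the maximum (which clips almost nothing on heavy-tailed
#' contact maps, hence not the default).
#'
#' @param map a `contact_map` or plain matrix.
#' @param q saturation level (default 0.995).
#' @param method `"quantile"` or `"fraction_of_max"`.
#' @return list with `matrix` (clipped) and `ceiling` (the colormap scale).
#' @export
saturate_for_display <- function(map, q = 0.995,
                                 method = c("quantile", "fraction_of_max")) {
  method <- match.arg(method)
  m <- if (inherits(map, "contact_map")) map$matrix else map
  if (length(m) == 0L) stop("empty map", call. = FALSE)
  pos <- m[m > 0]
  if (length(pos) == 0L) return(list(matrix = m, ceiling = 0))
  ceiling_val <- switch(method,
    quantile = stats::quantile(pos, q, names = FALSE),
    fraction_of_max = q * max(pos)
  )
  list(matrix = pmin(m, ceiling_val), ceiling = ceiling_val)
}
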