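#' Genome model with restriction-fragment boundaries
#'
#' Builds a circular (or linear) genome carrying restriction-site positions
#' and a binning resolution. Restriction sites are drawn as a Poisson process
#' along the genome, i.e. fragment lengths are i.i.d. exponential with the
#' requested mean, emulating a frequent 4-cutter digestion (mean spacing
#' 4^4 = 256 bp for an unbiased genome).
#'
#' Coordinates are 0-based, half-open: bin `i` covers
#' `[i * bin_size, (i + 1) * bin_size)`; fragment `k` starts at its recorded
#' boundary and runs to the next one (wrapping past the origin on a circular
#' genome). With no restriction site, a single fragment spans the genome.
#'
#' @param length_bp genome length in bp (> 0).
#' @param circular logical; circular chromosome (default `TRUE`).
#' @param mean_fragment_bp mean restriction-fragment length in bp (> 0).
#' @param bin_size_bp contact-map bin size in bp (default 5000).
#' @param seed integer seed; the model is a pure function of its arguments.
#' @return an object of class `genome_model`: a list with `length_bp`,
#'   `circular`, `fragment_boundaries` (sorted 0-based cut positions; may be
#'   a single 0 when no site was drawn), `n_fragments`, `bin_size_bp`,
#'   `n_bins`.
#' @examples
#' g <- generate_genome(100000, mean_fragment_bp = 256, seed = 1)
#' g$n_fragments
#' @export
generate_genome <- function(length_bp, circular = TRUE, mean_fragment_bp = 256,
                            bin_size_bp = 5000, seed = 1L) {
  stopifnot_scalar_pos(length_bp, "length_bp")
  stopifnot_scalar_pos(mean_fragment_bp, "mean_fragment_bp")
  stopifnot_scalar_pos(bin_size_bp, "bin_size_bp")
  set.seed(derive_seed(seed, 1L))
  # Poisson process of cut sites: draw ~50% more than expected, extend if short.
  n_exp <- length_bp / mean_fragment_bp
  gaps <- stats::rexp(ceiling(n_exp * 1.5) + 10, rate = 1 / mean_fragment_bp)
  pos <- cumsum(gaps)
  while (pos[length(pos)] < length_bp) {
    gaps <- stats::rexp(ceiling(n_exp * 0.5) + 10, rate = 1 / mean_fragment_bp)
    pos <- c(pos, pos[length(pos)] + cumsum(gaps))
  }
  cuts <- sort(unique(floor(pos[pos < length_bp])))
  if (length(cuts) == 0L) cuts <- 0
  structure(list(
    length_bp = as.numeric(length_bp),
    circular = isTRUE(circular),
    fragment_boundaries = as.numeric(cuts),
    n_fragments = length(cuts),
    bin_size_bp = as.numeric(bin_size_bp),
    n_bins = as.integer(ceiling(length_bp / bin_size_bp))
  ), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %.0f bp (%s), %d fragments (mean %.0f bp), %d bins of %.0f bp\n",
    x$length_bp, if (x$circular) "circular" else "linear",
    x$n_fragments, x$length_bp / x$n_fragments, x$n_bins, x$bin_size_bp
  ))
  invisible(x)
}

#' Fragment index of genomic positions
#'
#' Maps 0-based positions to 0-based fragment indices. On a circular genome
#' positions before the first recorded cut belong to the last fragment
#' (which wraps through the origin).
#'
#' @param genome a `genome_model`.
#' @param pos numeric vector of 0-based positions in `[0, length_bp)`.
#' @return integer vector of 0-based fragment indices.
#' @export
fragment_of <- function(genome, pos) {
  if (any(pos < 0 | pos >= genome$length_bp)) {
    stop("positions outside [0, length_bp)", call. = FALSE)
  }
  b <- genome$fragment_boundaries
  idx <- findInterval(pos, b) # 0 when pos < first cut
  if (genome$circular) {
    idx[idx == 0L] <- length(b) # wrap fragment
  } else {
    idx[idx == 0L] <- 1L
  }
  as.integer(idx - 1L)
}

#' Bin index of genomic positions
#'
#' @param genome a `genome_model`.
#' @param pos numeric vector of 0-based positions.
#' @return integer vector of 0-based bin indices.
#' @export
bin_of <- function(genome, pos) {
  if (any(pos < 0 | pos >= genome$length_bp)) {
    stop("positions outside [0, length_bp)", call. = FALSE)
  }
  as.integer(pos %/% genome$bin_size_bp)
}

# Circular fragment separation between fragment indices.
fragment_separation <- function(genome, f1, f2) {
  if (genome$circular) {
    circ_dist(f1, f2, genome$n_fragments)
  } else {
    abs(f1 - f2)
  }
}
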