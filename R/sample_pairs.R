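#' Noise model for non-informative pair events
#'
#' 3C/Hi-C libraries contain non-informative read pairs alongside true
#' religation products: self-circularized fragments (both reads on one
#' fragment, facing outward) and uncut fragments (reads on near-adjacent
#' fragments, facing inward). The generator plants these classes at the
#' given fractions so the classifier can be scored against truth.
#'
#' @param frac_self_circle fraction of planted self-circles in `[0, 1)`.
#' @param frac_uncut fraction of planted uncuts in `[0, 1)`.
#' @param uncut_max_fragments maximum fragment separation of planted uncuts
#'   (>= 1).
#' @return an object of class `pair_noise_model`.
#' @export
pair_noise_model <- function(frac_self_circle = 0.05, frac_uncut = 0.10,
                             uncut_max_fragments = 3L) {
  if (frac_self_circle < 0 || frac_uncut < 0 ||
      frac_self_circle + frac_uncut >= 1) {
    stop("noise fractions must be >= 0 and sum to < 1", call. = FALSE)
  }
  if (uncut_max_fragments < 1) stop("uncut_max_fragments must be >= 1", call. = FALSE)
  structure(list(frac_self_circle = frac_self_circle,
                 frac_uncut = frac_uncut,
                 uncut_max_fragments = as.integer(uncut_max_fragments)),
            class = "pair_noise_model")
}

# 0-based fragment start positions and circular lengths.
frag_geometry <- function(genome) {
  b <- genome$fragment_boundaries
  nxt <- c(b[-1], b[1] + genome$length_bp)
  list(start = b, len = nxt - b)
}

#' Sample ground-truthed read pairs from an expected contact matrix
#'
#' Draws `n_pairs` read pairs. Informative pairs pick a matrix cell with
#' probability proportional to the expected intensity (upper triangle,
#' diagonal included), place each read uniformly within its bin, snap it to
#' the containing restriction fragment, and assign all four strand
#' orientations with equal probability. Planted self-circles are
#' same-fragment, outward-facing (lower-position read on `-`); planted
#' uncuts are inward-facing (`+`, `-`) reads on fragments at most
#' `uncut_max_fragments` apart. Every record carries its true class.
#'
#' @param genome a `genome_model`.
#' @param expected_map a `contact_map` of expected intensities with the
#'   genome's bin count.
#' @param n_pairs number of pairs (> 0).
#' @param noise a `pair_noise_model`.
#' @param seed integer seed; output is a pure function of arguments.
#' @return a data.frame with columns `read_id`, `chr1`, `pos1`, `chr2`,
#'   `pos2`, `strand1`, `strand2`, `frag1`, `frag2`, `true_label`
#'   (positions 0-based bp; fragments 0-based indices; strand of the
#'   lower-position read first).
#' @export
sample_pairs <- function(genome, expected_map, n_pairs,
                         noise = pair_noise_model(), seed = 1L) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(expected_map, "contact_map"),
            inherits(noise, "pair_noise_model"))
  stopifnot_scalar_pos(n_pairs, "n_pairs")
  n <- genome$n_bins
  if (nrow(expected_map$matrix) != n) stop("map/genome bin mismatch", call. = FALSE)
  set.seed(derive_seed(seed, 2L))
  lab <- sample(c("informative", "self_circle", "uncut"), n_pairs, replace = TRUE,
                prob = c(1 - noise$frac_self_circle - noise$frac_uncut,
                         noise$frac_self_circle, noise$frac_uncut))
  pos1 <- pos2 <- numeric(n_pairs)
  s1 <- s2 <- character(n_pairs)
  fg <- frag_geometry(genome)
  L <- genome$length_bp
  b <- genome$bin_size_bp

  ii <- which(lab == "informative")
  if (length(ii)) {
    ut <- which(upper.tri(expected_map$matrix, diag = TRUE), arr.ind = TRUE)
    w <- expected_map$matrix[ut]
    cell <- ut[sample.int(nrow(ut), length(ii), replace = TRUE, prob = w), ,
               drop = FALSE]
    bin_a <- cell[, 1] - 1L
    bin_b <- cell[, 2] - 1L
    pa <- pmin(bin_a * b + stats::runif(length(ii)) * b, L - 1e-9)
    pb <- pmin(bin_b * b + stats::runif(length(ii)) * b, L - 1e-9)
    swap <- stats::runif(length(ii)) < 0.5
    pos1[ii] <- ifelse(swap, pb, pa)
    pos2[ii] <- ifelse(swap, pa, pb)
    s1[ii] <- sample(c("+", "-"), length(ii), replace = TRUE)
    s2[ii] <- sample(c("+", "-"), length(ii), replace = TRUE)
  }

  sc <- which(lab == "self_circle")
  if (length(sc)) {
    f <- sample.int(genome$n_fragments, length(sc), replace = TRUE,
                    prob = fg$len)
    u <- sort_pair(
      (fg$start[f] + stats::runif(length(sc)) * fg$len[f]) %% L,
      (fg$start[f] + stats::runif(length(sc)) * fg$len[f]) %% L
    )
    pos1[sc] <- u$lo
    pos2[sc] <- u$hi
    s1[sc] <- "-" # outward-facing: lower read points away (left), upper right
    s2[sc] <- "+"
  }

  uc <- which(lab == "uncut")
  if (length(uc)) {
    f1 <- sample.int(genome$n_fragments, length(uc), replace = TRUE,
                     prob = fg$len) - 1L
    sep <- sample.int(noise$uncut_max_fragments, length(uc), replace = TRUE)
    f2 <- (f1 + sep) %% genome$n_fragments
    u <- sort_pair(
      (fg$start[f1 + 1L] + stats::runif(length(uc)) * fg$len[f1 + 1L]) %% L,
      (fg$start[f2 + 1L] + stats::runif(length(uc)) * fg$len[f2 + 1L]) %% L
    )
    pos1[uc] <- u$lo
    pos2[uc] <- u$hi
    s1[uc] <- "+" # inward-facing: reads point toward each other
    s2[uc] <- "-"
  }

  pos1 <- floor(pos1)
  pos2 <- floor(pos2)
  data.frame(
    read_id = sprintf("pair%07d", seq_len(n_pairs)),
    chr1 = "chr", pos1 = pos1, chr2 = "chr", pos2 = pos2,
    strand1 = s1, strand2 = s2,
    frag1 = fragment_of(genome, pos1), frag2 = fragment_of(genome, pos2),
    true_label = lab,
    stringsAsFactors = FALSE
  )
}

sort_pair <- function(a, b) {
  list(lo = pmin(a, b), hi = pmax(a, b))
}

#' Pairs-table text I/O
#'
#' Tab-separated text with a `#columns:` header line; the first seven data
#' columns follow the 4DN `.pairs` column order
#' (readID chr1 pos1 chr2 pos2 strand1 strand2), then the two fragment
#' indices and any label columns present.
#'
#' @param pairs a pairs data.frame.
#' @param path file path.
#' @name pairs_io
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#columns: ", paste(names(pairs), collapse = " ")), con)
  utils::write.table(pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pairs_io
#' @export
read_pairs <- function(path) {
  header <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#columns:\\s*", "", header), "\\s+")[[1]]
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = cols, stringsAsFactors = FALSE)
  df
}
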