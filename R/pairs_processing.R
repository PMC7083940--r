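# Read-pair event classification and binning.
#
# 3C religation products are identified by the relative direction of the two
# reads and the distribution of the four strand configurations as a function
# of restriction-fragment separation: genuine trans-fragment religations show
# all four orientations equally often, while uncut fragments are enriched
# for inward-facing (+,-) pairs at short separations and self-circles for
# outward-facing (-,+) pairs.

# Orientation class of each pair, by the strand of the lower- then
# higher-position read: one of "++", "+-", "-+", "--".
pair_orientation <- function(pairs) {
  lo_first <- pairs$pos1 <= pairs$pos2
  lo <- ifelse(lo_first, pairs$strand1, pairs$strand2)
  hi <- ifelse(lo_first, pairs$strand2, pairs$strand1)
  paste0(lo, hi)
}

check_pair_columns <- function(pairs, cols) {
  miss <- setdiff(cols, names(pairs))
  if (length(miss)) {
    stop("pairs table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(pairs[cols]))) {
    stop("pairs table contains missing values in ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Strand-orientation frequencies by fragment separation
#'
#' For each circular fragment separation k in `0..k_max`, the frequency of
#' the four orientation classes (`++`, `+-`, `-+`, `--`) among pairs at that
#' separation. Separations with no pairs are returned as `NA` rows.
#'
#' @param pairs a pairs data.frame carrying strands and fragment indices.
#' @param genome a `genome_model` (supplies the fragment count for circular
#'   separations).
#' @param k_max largest separation scanned (default 50).
#' @return an object of class `orientation_profile`: list with `freq`
#'   (matrix, rows k = 0..k_max, columns `++`, `+-`, `-+`, `--`), `n` (pair
#'   count per k) and `k_max`.
#' @export
orientation_profile <- function(pairs, genome, k_max = 50L) {
  if (nrow(pairs) == 0L) stop("empty pairs table", call. = FALSE)
  check_pair_columns(pairs, c("pos1", "pos2", "strand1", "strand2",
                              "frag1", "frag2"))
  k <- fragment_separation(genome, pairs$frag1, pairs$frag2)
  ori <- pair_orientation(pairs)
  classes <- c("++", "+-", "-+", "--")
  keep <- k <= k_max
  tab <- table(factor(k[keep], levels = 0:k_max),
               factor(ori[keep], levels = classes))
  counts <- matrix(as.numeric(tab), nrow = k_max + 1L,
                   dimnames = list(0:k_max, classes))
  n <- rowSums(counts)
  freq <- counts / ifelse(n > 0, n, NA)
  structure(list(freq = freq, n = n, k_max = as.integer(k_max)),
            class = "orientation_profile")
}

#' Estimate uncut and self-circle separation thresholds
#'
#' Scans the orientation profile for the separation beyond which the
#' inward-facing (`+-`) and outward-facing (`-+`) frequencies have converged
#' to the 1/4 expected of genuine religations. The uncut threshold is the
#' largest separation k >= 1 whose `+-` frequency exceeds 0.25 by more than
#' `tolerance` and by more than 3 binomial standard errors (so sparsely
#' populated separations cannot register spurious excesses); the self-circle
#' threshold likewise for `-+`. Only an excess of the class's own
#' orientation counts: each non-informative class adds pairs of one specific
#' configuration, and the deficit it induces in the other three frequencies
#' is not evidence about those classes. Returns 0 when no excess exists.
#' Separation 0 (same fragment) is excluded: those pairs are discarded
#' unconditionally.
#'
#' @param profile an `orientation_profile`.
#' @param tolerance absolute deviation from 0.25 treated as converged
#'   (default 0.05).
#' @return list with `k_uncut` and `k_circle`.
#' @export
estimate_event_thresholds <- function(profile, tolerance = 0.05) {
  stopifnot(inherits(profile, "orientation_profile"))
  if (all(profile$n == 0)) stop("profile has no populated separations", call. = FALSE)
  ks <- seq_len(profile$k_max) # k >= 1
  n <- profile$n[as.character(ks)]
  se3 <- 3 * sqrt(0.25 * 0.75 / pmax(n, 1))
  last_excess <- function(class) {
    f <- profile$freq[as.character(ks), class]
    excess <- which(!is.na(f) & f - 0.25 > pmax(tolerance, se3))
    if (length(excess)) max(ks[excess]) else 0L
  }
  list(k_uncut = last_excess("+-"), k_circle = last_excess("-+"))
}

#' Classify read pairs into informative and non-informative events
#'
#' Same-fragment pairs are labeled `same_fragment` and always discarded
#' (whatever their orientation, including the outward-facing self-circle
#' geometry). Inward-facing (`+-`) pairs within `k_uncut` fragments are
#' labeled `uncut`; outward-facing (`-+`) pairs within `k_circle` fragments
#' `self_circle`; everything else `informative`. Input order is preserved.
#'
#' @param pairs pairs data.frame with strands and fragment indices.
#' @param genome a `genome_model`.
#' @param k_uncut,k_circle separation thresholds (>= 0), typically from
#'   [estimate_event_thresholds()].
#' @return the input data.frame with a `label` column appended (replaced if
#'   present).
#' @export
classify_pairs <- function(pairs, genome, k_uncut = 0L, k_circle = 0L) {
  if (k_uncut < 0 || k_circle < 0) stop("thresholds must be >= 0", call. = FALSE)
  check_pair_columns(pairs, c("pos1", "pos2", "strand1", "strand2",
                              "frag1", "frag2"))
  k <- fragment_separation(genome, pairs$frag1, pairs$frag2)
  ori <- pair_orientation(pairs)
  label <- rep("informative", nrow(pairs))
  label[ori == "+-" & k <= k_uncut] <- "uncut"
  label[ori == "-+" & k <= k_circle] <- "self_circle"
  label[k == 0L] <- "same_fragment"
  pairs$label <- label
  pairs
}

#' Bin informative pairs into a raw contact matrix
#'
#' Each pair labeled `informative` adds one count to the cell of its two
#' read bins and, off the diagonal, one to the transpose cell, so the matrix
#' is symmetric with total mass 2 x (off-diagonal pairs) + (diagonal pairs).
#'
#' @param pairs a labeled pairs data.frame (see [classify_pairs()]).
#' @param genome a `genome_model`.
#' @param bin_size_bp bin size (defaults to the genome's).
#' @return a raw-count `contact_map`.
#' @export
bin_contacts <- function(pairs, genome, bin_size_bp = genome$bin_size_bp) {
  if (bin_size_bp <= 0) stop("bin_size_bp must be > 0", call. = FALSE)
  if (is.null(pairs$label)) {
    stop("pairs must be classified first (no `label` column)", call. = FALSE)
  }
  n <- as.integer(ceiling(genome$length_bp / bin_size_bp))
  inf <- pairs[pairs$label == "informative", , drop = FALSE]
  m <- matrix(0, n, n)
  if (nrow(inf)) {
    b1 <- as.integer(inf$pos1 %/% bin_size_bp)
    b2 <- as.integer(inf$pos2 %/% bin_size_bp)
    counts <- table(b1 * n + b2)
    idx <- as.integer(names(counts))
    m[cbind(idx %/% n + 1L, idx %% n + 1L)] <-
      m[cbind(idx %/% n + 1L, idx %% n + 1L)] + as.numeric(counts)
    m <- m + t(m)
    diag(m) <- diag(m) / 2
  }
  contact_map(m, bin_size_bp, normalized = FALSE, circular = genome$circular)
}
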