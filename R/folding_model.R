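#' Parametric chromosome-folding truth
#'
#' Ground-truth description of a folded circular bacterial chromosome, used
#' to build closed-form expected contact maps and to sample read pairs. The
#' model combines, multiplicatively over a power-law distance decay:
#' chromatin interaction domain (CID) blocks, an anti-diagonal
#' replichore-cohesion band anchored at a parS-like locus, and a cross-shaped
#' anchor-versus-all signal; plus a uniform background floor.
#'
#' Defaults emulate a ~3.2 Mb *C. glutamicum*-like chromosome: the anchor at
#' 3.16 Mb (the parS cluster position, ~73 kb upstream of oriC at the origin
#' of the coordinate system), domains of a few hundred kb, a moderate decay
#' exponent typical of bacterial Hi-C at 5 kb resolution.
#'
#' @param decay_exponent power-law exponent \eqn{\alpha > 0} of the contact
#'   decay \eqn{P(s) \propto (1 + s)^{-\alpha}} (s in bins; the +1 keeps the
#'   diagonal finite).
#' @param arm_anchor_bp position (bp) of the parS-like anchor of the
#'   secondary diagonal.
#' @param arm_amplitude multiplicative strength A >= 0 of the anti-diagonal
#'   band; 0 disables it.
#' @param arm_width_bp Gaussian width (bp) of the band.
#' @param cid_boundaries_bp sorted domain-boundary positions (bp).
#' @param cid_contrast within- vs between-domain contact ratio (>= 1).
#' @param cross_amplitude multiplicative strength of anchor-versus-all
#'   contacts (the cross shape).
#' @param cross_width_bp Gaussian width (bp) of the cross arms.
#' @param noise_floor uniform background, as a fraction of the mean
#'   structured signal.
#' @return an object of class `folding_truth`.
#' @export
folding_truth <- function(decay_exponent = 0.7,
                          arm_anchor_bp = 3160000,
                          arm_amplitude = 1.0,
                          arm_width_bp = 50000,
                          cid_boundaries_bp = c(200, 550, 900, 1300, 1700,
                                                2100, 2450, 2800, 3000) * 1000,
                          cid_contrast = 1.5,
                          cross_amplitude = 0.3,
                          cross_width_bp = 50000,
                          noise_floor = 0.05) {
  if (decay_exponent <= 0) stop("decay_exponent must be > 0", call. = FALSE)
  if (arm_amplitude < 0) stop("arm_amplitude must be >= 0", call. = FALSE)
  if (cid_contrast < 1) stop("cid_contrast must be >= 1", call. = FALSE)
  if (is.unsorted(cid_boundaries_bp, strictly = TRUE)) {
    stop("cid_boundaries_bp must be strictly increasing", call. = FALSE)
  }
  structure(list(
    decay_exponent = decay_exponent,
    arm_anchor_bp = arm_anchor_bp,
    arm_amplitude = arm_amplitude,
    arm_width_bp = arm_width_bp,
    cid_boundaries_bp = cid_boundaries_bp,
    cid_contrast = cid_contrast,
    cross_amplitude = cross_amplitude,
    cross_width_bp = cross_width_bp,
    noise_floor = noise_floor
  ), class = "folding_truth")
}

#' Closed-form expected contact matrix under a folding truth
#'
#' Evaluates the folding model on the binned circular genome:
#' \deqn{E_{ij} = P(d_c(i,j)) \cdot c_{ij} \cdot (1 + A e^{-d_a(i,j)^2/2w^2})
#'   \cdot (1 + C (g_i + g_j)) + \eta \bar P}
#' with \eqn{d_c} the circular bin distance, \eqn{c_{ij}} the CID factor
#' (`cid_contrast` when i and j share a domain, 1 otherwise), \eqn{d_a} the
#' distance of (i, j) from the anti-diagonal through the anchor (the locus
#' where the two replichores are zipped together), \eqn{g_i} a Gaussian in
#' the circular distance of bin i from the anchor, and \eqn{\eta \bar P} a
#' uniform floor scaled to the mean structured signal.
#'
#' @param genome a `genome_model`.
#' @param truth a `folding_truth`; its anchor must lie inside the genome.
#' @return a `contact_map` of expected intensities (not normalized).
#' @export
expected_contact_matrix <- function(genome, truth) {
  stopifnot(inherits(genome, "genome_model"), inherits(truth, "folding_truth"))
  if (truth$arm_anchor_bp < 0 || truth$arm_anchor_bp >= genome$length_bp) {
    stop("arm anchor outside genome", call. = FALSE)
  }
  if (any(truth$cid_boundaries_bp < 0 | truth$cid_boundaries_bp >= genome$length_bp)) {
    stop("CID boundaries outside genome", call. = FALSE)
  }
  n <- genome$n_bins
  b <- genome$bin_size_bp
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  dc <- circ_dist(i, j, n)
  p <- (1 + dc)^(-truth$decay_exponent)

  # CID factor: domain id per bin from planted boundaries (circular: the
  # segment wrapping the origin is one domain).
  bounds_bin <- sort(unique(as.integer(truth$cid_boundaries_bp %/% b)))
  if (length(bounds_bin) >= 2) {
    dom <- findInterval(0:(n - 1), bounds_bin) %% length(bounds_bin)
    cid <- ifelse(outer(dom, dom, "=="), truth$cid_contrast, 1)
  } else {
    cid <- matrix(1, n, n)
  }

  # Anti-diagonal band through the anchor: points (a + s, a - s). The band
  # coordinate is the folded offset of (i + j) from 2a; the perpendicular
  # distance in bp is half that offset times the bin size.
  a <- truth$arm_anchor_bp / b # fractional anchor bin
  off <- fold_circ(i + j - 2 * a, n)
  d_anti_bp <- abs(off) / 2 * b
  band <- 1 + truth$arm_amplitude *
    exp(-d_anti_bp^2 / (2 * truth$arm_width_bp^2))

  # Cross: anchor row/column enrichment decaying with distance from anchor.
  g <- exp(-(circ_dist(0:(n - 1), a, n) * b)^2 / (2 * truth$cross_width_bp^2))
  cross <- 1 + truth$cross_amplitude * (outer(g, rep(1, n)) + outer(rep(1, n), g))

  m <- p * cid * band * cross
  m <- m + truth$noise_floor * mean(m)
  m <- (m + t(m)) / 2 # exact symmetry despite float rounding
  contact_map(m, b, normalized = FALSE, circular = genome$circular)
}
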