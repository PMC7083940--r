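# Comparison of normalized contact maps across strains/conditions: log2
# ratio maps, stratum-adjusted correlation (SCC) similarity, hierarchical
# grouping, and the strength of the secondary (anti-)diagonal.

#' Log2 ratio of two normalized contact maps
#'
#' Element-wise `log2(A / B)` over cells that are jointly valid and jointly
#' positive; all other cells are `NA` (masked), never infinite.
#'
#' @param mapA,mapB normalized `contact_map`s of equal shape and bin size.
#' @param labels character(2) names of numerator and denominator.
#' @return an object of class `ratio_map`: list with `matrix` (NA-masked),
#'   `joint_mask`, `bin_size_bp`, `labels`.
#' @export
log2_ratio <- function(mapA, mapB, labels = c("A", "B")) {
  stopifnot(inherits(mapA, "contact_map"), inherits(mapB, "contact_map"))
  if (!identical(dim(mapA$matrix), dim(mapB$matrix)) ||
      mapA$bin_size_bp != mapB$bin_size_bp) {
    stop("maps must share shape and bin size", call. = FALSE)
  }
  joint <- mapA$valid & mapB$valid
  r <- matrix(NA_real_, nrow(mapA$matrix), ncol(mapA$matrix))
  ok <- outer(joint, joint) & mapA$matrix > 0 & mapB$matrix > 0
  r[ok] <- log2(mapA$matrix[ok] / mapB$matrix[ok])
  structure(list(matrix = r, joint_mask = joint,
                 bin_size_bp = mapA$bin_size_bp, labels = labels),
            class = "ratio_map")
}

# Circular 2D box-filter mean of defined (non-NA) cells in a
# (2h+1) x (2h+1) window. Works on plain matrices; NA cells stay NA only
# where the whole window is undefined.
smooth_matrix <- function(m, h, circular = TRUE) {
  if (h == 0L) return(m)
  n <- nrow(m)
  vals <- ifelse(is.na(m), 0, m)
  def <- !is.na(m)
  acc <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (di in -h:h) {
    ri <- if (circular) ((seq_len(n) - 1 + di) %% n) + 1 else (seq_len(n) + di)
    for (dj in -h:h) {
      rj <- if (circular) ((seq_len(n) - 1 + dj) %% n) + 1 else (seq_len(n) + dj)
      if (circular) {
        acc <- acc + vals[ri, rj]
        cnt <- cnt + def[ri, rj]
      } else {
        oi <- ri >= 1 & ri <= n
        oj <- rj >= 1 & rj <= n
        acc[oi, oj] <- acc[oi, oj] + vals[ri[oi], rj[oj]]
        cnt[oi, oj] <- cnt[oi, oj] + def[ri[oi], rj[oj]]
      }
    }
  }
  out <- acc / ifelse(cnt > 0, cnt, NA)
  out
}

#' Smooth a contact map with a square mean filter
#'
#' Each cell is replaced by the mean of defined cells in the
#' `(2h+1) x (2h+1)` window centered on it; windows wrap on the circular
#' genome. `h = 0` returns the input unchanged. Masked bins are treated as
#' undefined and excluded from window means.
#'
#' @param map a `contact_map`.
#' @param h smoothing half-width in bins (the "smoothing index").
#' @return a `contact_map` with the smoothed matrix.
#' @export
smooth_map <- function(map, h = 3L) {
  stopifnot(inherits(map, "contact_map"))
  if (h < 0) stop("h must be >= 0", call. = FALSE)
  if (h == 0L) return(map)
  m <- map$matrix
  m[!map$valid, ] <- NA
  m[, !map$valid] <- NA
  sm <- smooth_matrix(m, as.integer(h), map$circular)
  sm[is.na(sm)] <- 0
  sm <- (sm + t(sm)) / 2
  contact_map(sm, map$bin_size_bp, map$valid, normalized = map$normalized,
              circular = map$circular)
}

#' Stratum-adjusted correlation coefficient between two maps
#'
#' HiCRep-style similarity: both maps are mean-filter smoothed with
#' half-width `h`, cells are stratified by circular diagonal distance, a
#' Pearson correlation is computed per stratum, and strata are combined with
#' weights `N_k * sd(A_k) * sd(B_k)`. Zero-variance or near-empty strata are
#' skipped.
#'
#' @param mapA,mapB normalized `contact_map`s of equal shape.
#' @param h smoothing half-width in bins (default 3).
#' @param max_dist_bp largest stratum distance (default 500 kb).
#' @return an object of class `similarity_result`: list with `scc`, `strata`
#'   (data.frame of per-stratum distance, n, correlation, weight), `h`,
#'   `max_dist_bp`.
#' @export
scc <- function(mapA, mapB, h = 3L, max_dist_bp = 500000) {
  stopifnot(inherits(mapA, "contact_map"), inherits(mapB, "contact_map"))
  if (!identical(dim(mapA$matrix), dim(mapB$matrix))) {
    stop("maps must share shape", call. = FALSE)
  }
  n <- nrow(mapA$matrix)
  joint <- mapA$valid & mapB$valid
  smA <- smooth_map(mapA, h)$matrix
  smB <- smooth_map(mapB, h)$matrix
  k_max <- min(n %/% 2L, as.integer(max_dist_bp %/% mapA$bin_size_bp))
  rows <- list()
  for (k in seq_len(k_max)) {
    i <- seq_len(n)
    j <- ((i - 1L + k) %% n) + 1L
    use <- joint[i] & joint[j]
    a <- smA[cbind(i[use], j[use])]
    b <- smB[cbind(i[use], j[use])]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3L) next
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 || sb == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      dist_bins = k, n = length(a), rho = stats::cor(a, b),
      weight = length(a) * sa * sb
    )
  }
  if (length(rows) == 0L) stop("no usable strata", call. = FALSE)
  strata <- do.call(rbind, rows)
  structure(list(
    scc = sum(strata$rho * strata$weight) / sum(strata$weight),
    strata = strata, h = as.integer(h), max_dist_bp = max_dist_bp
  ), class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> SCC = %.4f over %d strata (h = %d)\n",
              x$scc, nrow(x$strata), x$h))
  invisible(x)
}

#' Pairwise SCC matrix and hierarchical grouping of contact maps
#'
#' Computes all pairwise stratum-adjusted correlations and clusters the maps
#' by average-linkage hierarchical clustering on the distance `1 - SCC`.
#'
#' @param maps named list of normalized `contact_map`s (>= 2, equal shape).
#' @param h,max_dist_bp passed to [scc()].
#' @return list with `scc_matrix` (symmetric, unit diagonal), `hclust`, and
#'   `phylo` (an [ape::as.phylo()] dendrogram for Newick export).
#' @export
cluster_maps <- function(maps, h = 3L, max_dist_bp = 500000) {
  if (length(maps) < 2L) stop("need at least 2 maps", call. = FALSE)
  labels <- names(maps)
  if (is.null(labels)) labels <- paste0("map", seq_along(maps))
  k <- length(maps)
  s <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s[i, j] <- s[j, i] <- scc(maps[[i]], maps[[j]], h, max_dist_bp)$scc
    }
  }
  dimnames(s) <- list(labels, labels)
  d <- stats::as.dist(pmax(1 - s, 0))
  hc <- stats::hclust(d, method = "average")
  list(scc_matrix = s, hclust = hc, phylo = ape::as.phylo(hc))
}

#' Write a map-clustering dendrogram as Newick
#'
#' @param clustering result of [cluster_maps()].
#' @param path output file.
#' @export
write_newick <- function(clustering, path) {
  ape::write.tree(clustering$phylo, file = path)
  invisible(path)
}

#' Strength of the secondary (replichore-cohesion) diagonal
#'
#' The secondary diagonal collects cells `(anchor + s, anchor - s)`: loci
#' equidistant from the anchor on opposite chromosome arms. For each genomic
#' offset the profile reports the mean contact over cells within
#' `band_halfwidth_bins` of that anti-diagonal. The summary score is the
#' mean, over circular-distance strata, of
#' `log2(mean(band cells) / mean(off-band cells))` with off-band controls at
#' the same circular distance but anti-diagonal distance > 3x the
#' half-width. Comparing stratum means (rather than individual cells, whose
#' zeros would have to be dropped) keeps the score unbiased near zero on
#' sparse sampled maps. Strata closer than `min_dist_bins` to the main
#' diagonal are excluded so the score is not driven by the decay or domain
#' structure near the diagonal.
#'
#' @param map a normalized `contact_map`.
#' @param anchor_bp anchor position (bp) of the band (the parS-like locus).
#' @param band_halfwidth_bins half-width of the band in bins (default 2).
#' @param min_dist_bins smallest circular distance (bins) entering the score
#'   (default 10).
#' @return list with `profile` (data.frame `offset_bp`, `value`) and `score`
#'   (mean log2 band enrichment).
#' @export
secondary_diagonal_strength <- function(map, anchor_bp,
                                        band_halfwidth_bins = 2L,
                                        min_dist_bins = 10L) {
  stopifnot(inherits(map, "contact_map"))
  n <- nrow(map$matrix)
  if (2L * band_halfwidth_bins >= n) stop("band wider than map", call. = FALSE)
  if (anchor_bp < 0 || anchor_bp >= n * map$bin_size_bp) {
    stop("anchor outside genome", call. = FALSE)
  }
  a <- anchor_bp / map$bin_size_bp
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  dc <- circ_dist(i, j, n)
  d_anti <- abs(fold_circ(i + j - 2 * a, n)) / 2
  valid2 <- outer(map$valid, map$valid) & dc > 0
  in_band <- d_anti <= band_halfwidth_bins & valid2
  off_band <- d_anti > 3 * band_halfwidth_bins & valid2

  # profile over genomic offset
  offs <- sort(unique(dc[in_band]))
  prof <- vapply(offs, function(s) mean(map$matrix[in_band & dc == s]),
                 numeric(1))
  profile <- data.frame(offset_bp = offs * map$bin_size_bp, value = prof)

  # distance-matched log2 enrichment, stratum means vs stratum means
  score_terms <- c()
  for (s in offs[offs >= min_dist_bins]) {
    band_mean <- mean(map$matrix[in_band & dc == s])
    ctrl <- map$matrix[off_band & dc == s]
    if (length(ctrl) < 5L) next
    ctrl_mean <- mean(ctrl)
    if (band_mean <= 0 || ctrl_mean <= 0) next
    score_terms <- c(score_terms, log2(band_mean / ctrl_mean))
  }
  list(profile = profile,
       score = if (length(score_terms)) mean(score_terms) else NA_real_)
}
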