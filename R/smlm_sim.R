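# Synthetic single-molecule localization (PALM/SMLM) scenes with nested
# ground-truth clusters: per cell, macrocluster centers each carrying a ring
# of subcluster centers; emitters scatter around subcluster centers with a
# Gaussian footprint, blink over a short run of consecutive frames, and sit
# on a uniform in-cell background.

# --- polygon helpers (simple polygons, nm coordinates) ---

polygon_area_nm2 <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Ray-casting point-in-polygon with boundary points counted inside.
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # boundary check: point on segment (i, j)
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    within <- x >= pmin(xi, xj) - 1e-9 & x <= pmax(xi, xj) + 1e-9 &
      y >= pmin(yi, yj) - 1e-9 & y <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-6 * max(1, abs(xj - xi), abs(yj - yi)) & within)
    hit <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside | on_edge
}

sample_in_polygon <- function(n, poly) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, xr[1], xr[2]), stats::runif(m, yr[1], yr[2]))
    keep <- point_in_polygon(cand[, 1], cand[, 2], poly)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Ground truth for a synthetic SMLM scene
#'
#' Low-level constructor; most users build scenes with [smlm_scene()]. Cell
#' polygons are simple (non-self-intersecting) rings in nm; subcluster
#' centers must lie inside their cell.
#'
#' @param cells list of polygon matrices (2 columns, nm), one per cell.
#' @param macro_centers list (per cell) of 2-column matrices of macrocluster
#'   centers.
#' @param sub_centers list (per cell) of lists (per macro) of 2-column
#'   matrices of subcluster centers.
#' @param emitters_per_sub emitters placed around each subcluster center.
#' @param sub_sigma_nm Gaussian footprint SD of a subcluster (nm).
#' @param diffuse_emitters_per_macro emitters spread over the whole
#'   macrocluster footprint (the diffuse protein envelope on which the dense
#'   subclusters sit); 0 disables the envelope.
#' @param macro_sigma_nm Gaussian SD (nm) of the diffuse envelope.
#' @param background_rate uniform background, events per square micron.
#' @param photon_law,psf_law `c(meanlog, sdlog)` of log-normal photon-count
#'   and PSF-width (nm) distributions.
#' @param blink_probs probabilities of blink run lengths 1, 2, ... frames
#'   (consecutive frames only).
#' @param loc_jitter_nm per-event localization jitter SD (nm); small
#'   relative to the 30 nm grouping radius.
#' @param n_frames number of acquisition frames.
#' @return an object of class `smlm_truth`.
#' @export
smlm_truth <- function(cells, macro_centers, sub_centers,
                       emitters_per_sub = 118L, sub_sigma_nm = 12,
                       diffuse_emitters_per_macro = 180L, macro_sigma_nm = 80,
                       background_rate = 0.5,
                       photon_law = c(meanlog = log(150), sdlog = 0.3),
                       psf_law = c(meanlog = log(110), sdlog = 0.12),
                       blink_probs = c(0.5, 0.3, 0.2),
                       loc_jitter_nm = 4, n_frames = 10000L) {
  if (length(cells) == 0L) stop("empty cell list", call. = FALSE)
  stopifnot(length(macro_centers) == length(cells),
            length(sub_centers) == length(cells))
  for (ci in seq_along(cells)) {
    for (mi in seq_along(sub_centers[[ci]])) {
      sc <- sub_centers[[ci]][[mi]]
      if (!all(point_in_polygon(sc[, 1], sc[, 2], cells[[ci]]))) {
        stop("subcluster centers outside their cell polygon", call. = FALSE)
      }
    }
  }
  structure(list(
    cells = cells, macro_centers = macro_centers, sub_centers = sub_centers,
    emitters_per_sub = as.integer(emitters_per_sub),
    sub_sigma_nm = sub_sigma_nm,
    diffuse_emitters_per_macro = as.integer(diffuse_emitters_per_macro),
    macro_sigma_nm = macro_sigma_nm,
    background_rate = background_rate,
    photon_law = photon_law, psf_law = psf_law,
    blink_probs = blink_probs / sum(blink_probs),
    loc_jitter_nm = loc_jitter_nm, n_frames = as.integer(n_frames)
  ), class = "smlm_truth")
}

#' Build a regular multi-cell SMLM scene
#'
#' Lays out rod-shaped (rectangular) cells side by side, places
#' `macros_per_cell` macrocluster centers along each cell's long axis
#' `macro_sep_nm` apart, and arranges `subs_per_macro` subcluster centers on
#' a circle around each macro center with `sub_sep_nm` between adjacent
#' centers. Defaults mirror a ParB-like scene: two polar macroclusters,
#' each a diffuse ~80 nm protein envelope carrying three dense subclusters
#' of footprint 12 nm and ~200 events each once blinking is folded in. The
#' geometry is calibrated so the nested structure is the one the published
#' reachability cuts resolve: subcluster saddles sit between the 35 and
#' 50 nm reachability levels (separating subclusters while keeping each
#' macrocluster connected) and macrocluster gaps sit far above 50 nm.
#'
#' @param n_cells number of cells.
#' @param macros_per_cell,subs_per_macro cluster counts.
#' @param macro_sep_nm distance between adjacent macro centers.
#' @param sub_sep_nm distance between adjacent sub centers in a macro.
#' @param cell_length_nm,cell_width_nm cell rectangle dimensions.
#' @param ... further arguments passed to [smlm_truth()].
#' @return an `smlm_truth`.
#' @export
smlm_scene <- function(n_cells = 1L, macros_per_cell = 2L, subs_per_macro = 3L,
                       macro_sep_nm = 500, sub_sep_nm = 150,
                       cell_length_nm = 2500, cell_width_nm = 900, ...) {
  cells <- list(); macro_centers <- list(); sub_centers <- list()
  gap <- 500
  for (ci in seq_len(n_cells)) {
    x0 <- (ci - 1) * (cell_length_nm + gap)
    poly <- cbind(c(x0, x0 + cell_length_nm, x0 + cell_length_nm, x0),
                  c(0, 0, cell_width_nm, cell_width_nm))
    cx <- x0 + cell_length_nm / 2
    cy <- cell_width_nm / 2
    offs <- (seq_len(macros_per_cell) - (macros_per_cell + 1) / 2) * macro_sep_nm
    mc <- cbind(cx + offs, rep(cy, macros_per_cell))
    subs <- lapply(seq_len(macros_per_cell), function(mi) {
      if (subs_per_macro == 1L) {
        mc[mi, , drop = FALSE]
      } else {
        r <- sub_sep_nm / (2 * sin(pi / subs_per_macro))
        ang <- 2 * pi * (seq_len(subs_per_macro) - 1) / subs_per_macro
        cbind(mc[mi, 1] + r * cos(ang), mc[mi, 2] + r * sin(ang))
      }
    })
    cells[[ci]] <- poly
    macro_centers[[ci]] <- mc
    sub_centers[[ci]] <- subs
  }
  smlm_truth(cells, macro_centers, sub_centers, ...)
}

#' Simulate a localization table from an SMLM truth
#'
#' Each emitter draws its position from a Gaussian around its subcluster
#' center, a blink run length (consecutive frames, no gaps), and emits one
#' event per on-frame, each jittered by the localization error. Background
#' events are uniform within each cell polygon. Photon counts and PSF widths
#' follow the truth's log-normal laws.
#'
#' @param truth an `smlm_truth`.
#' @param seed integer seed; output is a pure function of (truth, seed).
#' @return a data.frame sorted by frame with columns `id`, `frame`, `x_nm`,
#'   `y_nm`, `photons`, `psf_width_nm` and truth columns `true_cell`,
#'   `true_macro`, `true_sub`, `true_emitter` (`NA` for background).
#' @export
simulate_localizations <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "smlm_truth"))
  set.seed(derive_seed(seed, 3L))
  rows <- list()
  emitter_id <- 0L
  emit <- function(ex, ey, ci, mi, si) {
    ne <- length(ex)
    if (ne == 0L) return(invisible())
    runs <- sample.int(length(truth$blink_probs), ne, replace = TRUE,
                       prob = truth$blink_probs)
    f0 <- sample.int(truth$n_frames - length(truth$blink_probs), ne,
                     replace = TRUE)
    for (e in seq_len(ne)) {
      emitter_id <<- emitter_id + 1L
      L <- runs[e]
      rows[[length(rows) + 1L]] <<- data.frame(
        frame = f0[e] + 0:(L - 1L),
        x_nm = ex[e] + stats::rnorm(L, 0, truth$loc_jitter_nm),
        y_nm = ey[e] + stats::rnorm(L, 0, truth$loc_jitter_nm),
        true_cell = ci, true_macro = mi, true_sub = si,
        true_emitter = emitter_id
      )
    }
    invisible()
  }
  for (ci in seq_along(truth$cells)) {
    for (mi in seq_along(truth$sub_centers[[ci]])) {
      sc <- truth$sub_centers[[ci]][[mi]]
      for (si in seq_len(nrow(sc))) {
        ne <- truth$emitters_per_sub
        emit(stats::rnorm(ne, sc[si, 1], truth$sub_sigma_nm),
             stats::rnorm(ne, sc[si, 2], truth$sub_sigma_nm), ci, mi, si)
      }
      nd <- truth$diffuse_emitters_per_macro
      if (nd > 0L) {
        mc <- truth$macro_centers[[ci]][mi, ]
        emit(stats::rnorm(nd, mc[1], truth$macro_sigma_nm),
             stats::rnorm(nd, mc[2], truth$macro_sigma_nm),
             ci, mi, NA_integer_)
      }
    }
    area_um2 <- polygon_area_nm2(truth$cells[[ci]]) / 1e6
    nbg <- stats::rpois(1, truth$background_rate * area_um2)
    if (nbg > 0) {
      bg <- sample_in_polygon(nbg, truth$cells[[ci]])
      rows[[length(rows) + 1L]] <- data.frame(
        frame = sample.int(truth$n_frames, nbg, replace = TRUE),
        x_nm = bg[, 1], y_nm = bg[, 2],
        true_cell = ci, true_macro = NA_integer_, true_sub = NA_integer_,
        true_emitter = NA_integer_
      )
    }
  }
  ev <- do.call(rbind, rows)
  ne <- nrow(ev)
  ev$photons <- stats::rlnorm(ne, truth$photon_law[1], truth$photon_law[2])
  ev$psf_width_nm <- stats::rlnorm(ne, truth$psf_law[1], truth$psf_law[2])
  ev <- ev[order(ev$frame, ev$x_nm), , drop = FALSE]
  ev$id <- seq_len(ne)
  rownames(ev) <- NULL
  ev[, c("id", "frame", "x_nm", "y_nm", "photons", "psf_width_nm",
         "true_cell", "true_macro", "true_sub", "true_emitter")]
}

#' Localization-table and polygon text I/O
#'
#' Localizations are CSV with header `id, frame, x_nm, y_nm, photons,
#' psf_width_nm` (truth columns, when present, are appended). Cell outlines
#' are WKT `POLYGON` text, one cell per line.
#'
#' @param events localization data.frame.
#' @param path file path.
#' @name smlm_io
#' @export
write_localizations <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname smlm_io
#' @export
read_localizations <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    stop("no localization events in file: ", path, call. = FALSE)
  }
  df
}

#' @rdname smlm_io
#' @param polygons list of 2-column polygon matrices.
#' @export
write_polygons_wkt <- function(polygons, path) {
  lines <- vapply(polygons, function(p) {
    ring <- rbind(p, p[1, ]) # close the ring
    sprintf("POLYGON ((%s))",
            paste(sprintf("%.3f %.3f", ring[, 1], ring[, 2]), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname smlm_io
#' @export
read_polygons_wkt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    body <- sub("^\\s*POLYGON\\s*\\(\\(", "", l)
    body <- sub("\\)\\)\\s*$", "", body)
    pts <- do.call(rbind, lapply(strsplit(body, ",")[[1]], function(p) {
      as.numeric(strsplit(trimws(p), "\\s+")[[1]])
    }))
    if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ])) {
      pts <- pts[-nrow(pts), , drop = FALSE]
    }
    pts
  })
}
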