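# PALM/SMLM cluster analysis: event quality filtering, blink grouping,
# cell assignment, OPTICS reachability ordering, and nested macro-/sub-
# cluster extraction by horizontal reachability cuts.

#' Filter localization events on photon count and PSF width
#'
#' Keeps events with `photon_min <= photons <= photon_max` and
#' `psf_min <= psf_width_nm <= psf_max`; all bounds inclusive. Defaults are
#' the standard PALM quality window for PAmCherry (70-350 photons, PSF width
#' at 1/e maximum 70-170 nm), excluding background and co-emission events.
#'
#' @param events localization data.frame with `photons` and `psf_width_nm`.
#' @param photon_min,photon_max photon-count bounds.
#' @param psf_min,psf_max PSF-width bounds (nm).
#' @return the surviving rows, with attributes `n_kept` and `n_removed`.
#' @export
filter_events <- function(events, photon_min = 70, photon_max = 350,
                          psf_min = 70, psf_max = 170) {
  if (!all(c("photons", "psf_width_nm") %in% names(events))) {
    stop("events must carry `photons` and `psf_width_nm`", call. = FALSE)
  }
  keep <- events$photons >= photon_min & events$photons <= photon_max &
    events$psf_width_nm >= psf_min & events$psf_width_nm <= psf_max
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Group blinking events into molecules
#'
#' Events in consecutive frames (at most `max_off_frames` dark frames
#' allowed) lying within `radius_nm` of the running photon-weighted group
#' centroid are merged into one molecule; a group spanning `max_on_frames`
#' on-frames is closed greedily. Each group absorbs at most one event per
#' frame. One output record per group with the photon-weighted centroid,
#' summed photons and mean PSF width.
#'
#' @param events localization data.frame sorted by frame.
#' @param max_on_frames maximum on-frames per group (default 3).
#' @param max_off_frames dark frames allowed inside a run (default 0).
#' @param radius_nm search radius to the group centroid (default 30).
#' @return data.frame of grouped molecules: `id`, `frame` (first), `x_nm`,
#'   `y_nm`, `photons`, `psf_width_nm`, `n_events`.
#' @export
group_events <- function(events, max_on_frames = 3L, max_off_frames = 0L,
                         radius_nm = 30) {
  if (radius_nm < 0) stop("radius_nm must be >= 0", call. = FALSE)
  if (is.unsorted(events$frame)) {
    stop("events must be sorted by frame", call. = FALSE)
  }
  n <- nrow(events)
  group_id <- integer(n)
  # active groups: parallel vectors
  g_x <- g_y <- g_w <- numeric(0)    # centroid and photon weight
  g_last <- g_frames <- integer(0)   # last frame, on-frame count
  g_idx <- integer(0)                # group output index
  n_groups <- 0L
  for (r in seq_len(n)) {
    f <- events$frame[r]
    # retire groups too old to accept this frame
    live <- g_last >= f - 1L - max_off_frames
    g_x <- g_x[live]; g_y <- g_y[live]; g_w <- g_w[live]
    g_last <- g_last[live]; g_frames <- g_frames[live]; g_idx <- g_idx[live]
    x <- events$x_nm[r]; y <- events$y_nm[r]; w <- events$photons[r]
    cand <- which(g_last < f) # one event per frame per group
    assigned <- FALSE
    if (length(cand)) {
      d2 <- (g_x[cand] - x)^2 + (g_y[cand] - y)^2
      best <- cand[which.min(d2)]
      if (min(d2) <= radius_nm^2) {
        group_id[r] <- g_idx[best]
        tw <- g_w[best] + w
        g_x[best] <- (g_x[best] * g_w[best] + x * w) / tw
        g_y[best] <- (g_y[best] * g_w[best] + y * w) / tw
        g_w[best] <- tw
        g_last[best] <- f
        g_frames[best] <- g_frames[best] + 1L
        if (g_frames[best] >= max_on_frames) { # close greedily
          keep <- seq_along(g_x) != best
          g_x <- g_x[keep]; g_y <- g_y[keep]; g_w <- g_w[keep]
          g_last <- g_last[keep]; g_frames <- g_frames[keep]
          g_idx <- g_idx[keep]
        }
        assigned <- TRUE
      }
    }
    if (!assigned) {
      n_groups <- n_groups + 1L
      group_id[r] <- n_groups
      if (max_on_frames > 1L) {
        g_x <- c(g_x, x); g_y <- c(g_y, y); g_w <- c(g_w, w)
        g_last <- c(g_last, f); g_frames <- c(g_frames, 1L)
        g_idx <- c(g_idx, n_groups)
      }
    }
  }
  w <- events$photons
  agg <- function(v, fun) as.numeric(tapply(v, group_id, fun))
  ids <- sort(unique(group_id))
  sum_w <- as.numeric(tapply(w, group_id, sum))
  data.frame(
    id = ids,
    frame = as.integer(tapply(events$frame, group_id, min)),
    x_nm = as.numeric(tapply(events$x_nm * w, group_id, sum)) / sum_w,
    y_nm = as.numeric(tapply(events$y_nm * w, group_id, sum)) / sum_w,
    photons = sum_w,
    psf_width_nm = agg(events$psf_width_nm, mean),
    n_events = as.integer(tapply(w, group_id, length))
  )
}

#' Assign localization events to cells
#'
#' Point-in-polygon assignment against the cell outlines; boundary points
#' count as inside. Events falling in no polygon are dropped; an event
#' falling in more than one polygon raises an error (overlapping outlines
#' make the assignment ambiguous).
#'
#' @param events localization data.frame with `x_nm`, `y_nm`.
#' @param cell_polygons list of simple 2-column polygon matrices (nm).
#' @return events with a `cell_id` column (index into `cell_polygons`);
#'   attribute `n_dropped`.
#' @export
assign_cells <- function(events, cell_polygons) {
  hits <- sapply(cell_polygons, function(p) {
    point_in_polygon(events$x_nm, events$y_nm, p)
  })
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = nrow(events))
  n_hits <- rowSums(hits)
  if (any(n_hits > 1L)) {
    stop("overlapping cell polygons: ambiguous assignment", call. = FALSE)
  }
  keep <- n_hits == 1L
  out <- events[keep, , drop = FALSE]
  out$cell_id <- apply(hits[keep, , drop = FALSE], 1, which)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' OPTICS reachability ordering
#'
#' Standard OPTICS over 2D points of one cell. The core distance of a point
#' is its distance to the `minpts`-th closest point (the point itself
#' counted first), undefined (`NA`) when fewer than `minpts` points lie
#' within `epsilon_nm`. The reachability of q from p is
#' `max(core(p), dist(p, q))`; points are emitted in order of smallest
#' pending reachability. Ties and new-component starts are broken by lowest
#' point index, so the ordering is deterministic.
#'
#' @param points 2-column matrix or data.frame with `x_nm`, `y_nm`.
#' @param minpts minimum points defining density (default 32).
#' @param epsilon_nm maximum search radius (default 3000, chosen to span a
#'   whole bacterial cell so no in-cell structure is truncated).
#' @return an object of class `optics_ordering`: list with `order` (visit
#'   order, 1-based indices), `reachability` (per ordered position; `Inf`
#'   opens each new component), `core_distance` (per point, `NA` if
#'   undefined), `minpts`, `epsilon_nm`, `n`.
#' @export
optics <- function(points, minpts = 32L, epsilon_nm = 3000) {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (n == 0L) stop("no points", call. = FALSE)
  D <- as.matrix(stats::dist(xy))
  core <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- sort.int(D[i, ], method = "quick")[minpts] # position 1 is self (0)
    if (!is.na(d) && d <= epsilon_nm) core[i] <- d
  }
  processed <- rep(FALSE, n)
  ord <- integer(n)
  reach_out <- numeric(n)
  r_seed <- rep(Inf, n)
  in_seeds <- rep(FALSE, n)
  pos <- 0L
  update_seeds <- function(p) {
    if (is.na(core[p])) return(invisible())
    nb <- which(!processed & D[p, ] <= epsilon_nm)
    newr <- pmax(core[p], D[p, nb])
    better <- newr < r_seed[nb]
    r_seed[nb[better]] <<- newr[better]
    in_seeds[nb[better]] <<- TRUE
    invisible()
  }
  for (start in seq_len(n)) {
    if (processed[start]) next
    processed[start] <- TRUE
    pos <- pos + 1L
    ord[pos] <- start
    reach_out[pos] <- Inf
    update_seeds(start)
    while (any(in_seeds)) {
      cand <- which(in_seeds)
      q <- cand[which.min(r_seed[cand])] # ties: lowest index
      in_seeds[q] <- FALSE
      processed[q] <- TRUE
      pos <- pos + 1L
      ord[pos] <- q
      reach_out[pos] <- r_seed[q]
      update_seeds(q)
    }
    r_seed[] <- Inf
    in_seeds[] <- FALSE
  }
  structure(list(order = ord, reachability = reach_out, core_distance = core,
                 minpts = as.integer(minpts), epsilon_nm = epsilon_nm, n = n),
            class = "optics_ordering")
}

as_xy <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x_nm", "y_nm") %in% names(points)))
    cbind(points$x_nm, points$y_nm)
  } else {
    as.matrix(points)
  }
}

#' @export
print.optics_ordering <- function(x, ...) {
  cat(sprintf("<optics_ordering> %d points, minpts = %d, epsilon = %g nm, %d core points\n",
              x$n, x$minpts, x$epsilon_nm, sum(!is.na(x$core_distance))))
  invisible(x)
}

#' Extract clusters from a reachability ordering at a horizontal cut
#'
#' ExtractDBSCAN semantics: scanning the ordering, a reachability above the
#' threshold closes the current cluster; the closing point opens a new
#' cluster iff its own core distance is within the threshold, otherwise it
#' is noise. Clusters with fewer than `minpts` points are demoted to noise.
#'
#' @param ordering an `optics_ordering`.
#' @param threshold_nm horizontal reachability cut (> 0, <= epsilon).
#' @param minpts minimum cluster size (defaults to the ordering's).
#' @return integer cluster labels per point (original indexing); 0 = noise.
#' @export
extract_clusters <- function(ordering, threshold_nm,
                             minpts = ordering$minpts) {
  stopifnot(inherits(ordering, "optics_ordering"))
  if (threshold_nm <= 0) stop("threshold must be > 0", call. = FALSE)
  if (threshold_nm > ordering$epsilon_nm) {
    stop("threshold exceeds epsilon", call. = FALSE)
  }
  n <- ordering$n
  labels <- integer(n)
  current <- 0L
  next_id <- 0L
  for (k in seq_len(n)) {
    i <- ordering$order[k]
    if (ordering$reachability[k] > threshold_nm) {
      cd <- ordering$core_distance[i]
      if (!is.na(cd) && cd <= threshold_nm) {
        next_id <- next_id + 1L
        current <- next_id
        labels[i] <- current
      } else {
        current <- 0L
        labels[i] <- 0L
      }
    } else {
      labels[i] <- current
    }
  }
  # demote undersized clusters, renumber by first appearance in the ordering
  sizes <- tabulate(labels, nbins = max(labels, 1L))
  small <- which(sizes < minpts)
  labels[labels %in% small] <- 0L
  surviving <- unique(labels[ordering$order])
  surviving <- surviving[surviving != 0L]
  relabel <- integer(max(labels, 1L))
  relabel[surviving] <- seq_along(surviving)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  labels
}

#' Nested macro- and subcluster assignment
#'
#' Macroclusters are extracted at the `macro_nm` reachability cut and
#' subclusters at the tighter `sub_nm` cut of the same ordering; every
#' sub-labeled point necessarily lies inside a macrocluster (asserted).
#'
#' @param ordering an `optics_ordering`.
#' @param macro_nm,sub_nm reachability thresholds (defaults 50 and 35 nm).
#' @param minpts minimum cluster size (defaults to the ordering's).
#' @return an object of class `cluster_assignment`: list with `macro` and
#'   `sub` integer labels per point (0 = noise/none), the `ordering`, and
#'   the thresholds.
#' @export
nested_clusters <- function(ordering, macro_nm = 50, sub_nm = 35,
                            minpts = ordering$minpts) {
  if (sub_nm > macro_nm) stop("sub_nm must be <= macro_nm", call. = FALSE)
  macro <- extract_clusters(ordering, macro_nm, minpts)
  sub <- extract_clusters(ordering, sub_nm, minpts)
  if (any(sub > 0L & macro == 0L)) {
    stop("internal error: subcluster outside any macrocluster", call. = FALSE)
  }
  structure(list(macro = macro, sub = sub, ordering = ordering,
                 macro_nm = macro_nm, sub_nm = sub_nm,
                 minpts = as.integer(minpts)),
            class = "cluster_assignment")
}

#' Per-cell macrocluster statistics
#'
#' For each macrocluster: event count, number of distinct subclusters, and
#' mean (finite) reachability of its members. Per cell, the two
#' macroclusters with the most events are flagged (`top2`); ties are broken
#' by smaller mean reachability (the tighter cluster). Cells without
#' macroclusters contribute no rows.
#'
#' @param assignments named list of `cluster_assignment` objects, one per
#'   cell; names are the cell ids.
#' @return data.frame with columns `cell_id`, `macro`, `n_events`, `n_sub`,
#'   `mean_reach_nm`, `top2`.
#' @export
cluster_stats <- function(assignments) {
  rows <- list()
  for (cell in names(assignments)) {
    asg <- assignments[[cell]]
    macros <- sort(unique(asg$macro[asg$macro > 0L]))
    if (length(macros) == 0L) next
    reach_of <- numeric(asg$ordering$n)
    reach_of[asg$ordering$order] <- asg$ordering$reachability
    df <- do.call(rbind, lapply(macros, function(m) {
      members <- which(asg$macro == m)
      subs <- unique(asg$sub[members])
      r <- reach_of[members]
      data.frame(cell_id = cell, macro = m,
                 n_events = length(members),
                 n_sub = sum(subs > 0L),
                 mean_reach_nm = mean(r[is.finite(r)]))
    }))
    o <- order(-df$n_events, df$mean_reach_nm)
    df$top2 <- seq_len(nrow(df)) %in% o[seq_len(min(2L, nrow(df)))]
    rows[[length(rows) + 1L]] <- df
  }
  if (length(rows) == 0L) {
    return(data.frame(cell_id = character(0), macro = integer(0),
                      n_events = integer(0), n_sub = integer(0),
                      mean_reach_nm = numeric(0), top2 = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare cluster statistics between two conditions
#'
#' Two-tailed Kruskal-Wallis rank-sum tests (with tie correction) on events
#' per macrocluster and on subclusters per macrocluster, restricted to the
#' two biggest macroclusters per cell (`top2`).
#'
#' @param statsA,statsB [cluster_stats()] tables for the two conditions.
#' @param labels condition names.
#' @return data.frame with one row per metric: `metric`, `chisq`, `df`, `p`,
#'   `nA`, `nB`.
#' @export
compare_conditions <- function(statsA, statsB, labels = c("A", "B")) {
  a <- statsA[statsA$top2, , drop = FALSE]
  b <- statsB[statsB$top2, , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("need >= 2 macroclusters per condition", call. = FALSE)
  }
  one <- function(metric) {
    x <- c(a[[metric]], b[[metric]])
    g <- factor(rep(labels, c(nrow(a), nrow(b))))
    if (length(unique(x)) == 1L) {
      # fully tied data carry no rank information: no detectable difference
      return(data.frame(metric = metric, chisq = 0, df = 1, p = 1,
                        nA = nrow(a), nB = nrow(b)))
    }
    kt <- stats::kruskal.test(x, g)
    data.frame(metric = metric, chisq = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value,
               nA = nrow(a), nB = nrow(b))
  }
  rbind(one("n_events"), one("n_sub"))
}
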