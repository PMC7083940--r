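# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain loops and from-scratch recomputation.

# Brute-force OPTICS: at every step the pending reachability of every
# unprocessed point is recomputed from scratch as the minimum over all
# processed core points p of max(core(p), d(p, q)) with d <= eps; the next
# point is the unprocessed one with the smallest pending reachability
# (ties and exhausted components fall back to lowest index).
oracle_optics <- function(xy, minpts, eps) {
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  core <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- sort(D[i, ])
    if (length(s) >= minpts && s[minpts] <= eps) core[i] <- s[minpts]
  }
  processed <- rep(FALSE, n)
  ord <- integer(n)
  reach <- numeric(n)
  for (pos in seq_len(n)) {
    un <- which(!processed)
    pr <- which(processed & !is.na(core))
    r <- rep(Inf, length(un))
    if (length(pr)) {
      for (qi in seq_along(un)) {
        q <- un[qi]
        dd <- D[pr, q]
        ok <- dd <= eps
        if (any(ok)) r[qi] <- min(pmax(core[pr[ok]], dd[ok]))
      }
    }
    if (all(is.infinite(r))) {
      nxt <- un[1] # lowest index opens a new component
    } else {
      nxt <- un[which.min(r)] # which.min takes the lowest index on ties
    }
    ord[pos] <- nxt
    reach[pos] <- r[match(nxt, un)]
    processed[nxt] <- TRUE
  }
  list(order = ord, reachability = reach, core_distance = core)
}

# Winding-number point-in-polygon (boundary counted inside).
oracle_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  out <- logical(length(x))
  for (k in seq_along(x)) {
    wn <- 0
    on <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- poly[i, 1]; y1 <- poly[i, 2]
      x2 <- poly[j, 1]; y2 <- poly[j, 2]
      cr <- (x2 - x1) * (y[k] - y1) - (y2 - y1) * (x[k] - x1)
      if (abs(cr) < 1e-9 &&
          x[k] >= min(x1, x2) - 1e-9 && x[k] <= max(x1, x2) + 1e-9 &&
          y[k] >= min(y1, y2) - 1e-9 && y[k] <= max(y1, y2) + 1e-9) {
        on <- TRUE
        break
      }
      if (y1 <= y[k]) {
        if (y2 > y[k] && cr > 0) wn <- wn + 1
      } else {
        if (y2 <= y[k] && cr < 0) wn <- wn - 1
      }
    }
    out[k] <- on || wn != 0
  }
  out
}

# Independent alternating-scaling (Sinkhorn-Knopp) reference: scaling-vector
# form, run to tight convergence, returns diag(r) %*% M %*% diag(c).
oracle_sinkhorn <- function(m, tol = 1e-12, max_iter = 10000) {
  r <- rep(1, nrow(m))
  cvec <- rep(1, ncol(m))
  for (it in seq_len(max_iter)) {
    r <- 1 / as.vector(m %*% cvec)
    cvec <- 1 / as.vector(crossprod(m, r))
    s <- sweep(sweep(m, 1, r, "*"), 2, cvec, "*")
    if (max(abs(rowSums(s) - 1)) < tol && max(abs(colSums(s) - 1)) < tol) break
  }
  s
}

# Brute-force (2h+1)^2 circular window mean ignoring NA.
oracle_smooth <- function(m, h) {
  n <- nrow(m)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      vals <- c()
      for (di in -h:h) {
        for (dj in -h:h) {
          vals <- c(vals, m[((i - 1 + di) %% n) + 1, ((j - 1 + dj) %% n) + 1])
        }
      }
      out[i, j] <- mean(vals, na.rm = TRUE)
    }
  }
  out[is.nan(out)] <- NA
  out
}

# Hand Kruskal-Wallis with tie correction.
oracle_kruskal <- function(x, g) {
  N <- length(x)
  rk <- rank(x)
  groups <- split(rk, g)
  H <- 12 / (N * (N + 1)) * sum(vapply(groups, function(r) sum(r)^2 / length(r),
                                       numeric(1))) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Small deterministic localization table for filter/group oracles.
toy_events <- function() {
  data.frame(
    id = 1:10,
    frame = c(1, 1, 2, 2, 3, 5, 5, 6, 8, 9),
    x_nm = c(100, 500, 104, 502, 98, 300, 900, 302, 305, 700),
    y_nm = c(100, 500, 102, 498, 101, 300, 900, 299, 301, 700),
    photons = c(100, 200, 150, 500, 120, 90, 80, 110, 60, 200),
    psf_width_nm = c(120, 110, 100, 130, 90, 160, 180, 150, 120, 65)
  )
}

# Two-condition folding truths for a small (800 kb) test genome.
small_genome <- function(seed = 1) {
  generate_genome(800000, mean_fragment_bp = 256, bin_size_bp = 5000,
                  seed = seed)
}

small_truth <- function(arm_amplitude = 1, cid_contrast = 1.5,
                        cross_amplitude = 0.3) {
  folding_truth(arm_anchor_bp = 700000, arm_amplitude = arm_amplitude,
                cid_boundaries_bp = c(150, 400, 650) * 1000,
                cid_contrast = cid_contrast,
                cross_amplitude = cross_amplitude)
}
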