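test_that("event filtering applies inclusive photon and PSF bounds", {
  ev <- toy_events()
  out <- filter_events(ev)
  # brute-force row scan
  keep <- ev$photons >= 70 & ev$photons <= 350 &
    ev$psf_width_nm >= 70 & ev$psf_width_nm <= 170
  expect_equal(out$id, ev$id[keep])
  expect_equal(attr(out, "n_removed"), sum(!keep))

  # bounds are inclusive
  edge <- data.frame(photons = c(70, 350, 69.9, 350.1),
                     psf_width_nm = c(70, 170, 120, 120))
  expect_equal(nrow(filter_events(edge)), 2L)
  expect_error(filter_events(data.frame(photons = 1)), "psf_width_nm")
})

test_that("blink grouping merges consecutive-frame events within the radius", {
  # two events one frame apart, 10 nm apart: one photon-weighted molecule
  ev <- data.frame(id = 1:2, frame = c(1, 2), x_nm = c(0, 10), y_nm = c(0, 0),
                   photons = c(100, 300), psf_width_nm = c(100, 100))
  g <- group_events(ev)
  expect_equal(nrow(g), 1L)
  expect_equal(g$x_nm, (0 * 100 + 10 * 300) / 400)
  expect_equal(g$photons, 400)
  expect_equal(g$n_events, 2L)

  # a dark frame beyond max_off splits the run
  ev2 <- ev
  ev2$frame <- c(1, 3)
  expect_equal(nrow(group_events(ev2)), 2L)
  expect_equal(nrow(group_events(ev2, max_off_frames = 1)), 1L)

  # outside the radius never merges; runs longer than max_on split greedily
  ev3 <- ev
  ev3$x_nm <- c(0, 100)
  expect_equal(nrow(group_events(ev3)), 2L)
  run5 <- data.frame(id = 1:5, frame = 1:5, x_nm = rep(0, 5), y_nm = 0:4,
                     photons = 100, psf_width_nm = 100)
  expect_equal(group_events(run5)$n_events, c(3L, 2L))

  # generator oracle: with contiguous blinks and no background the group
  # count equals the planted emitter count
  tr <- smlm_scene(n_cells = 1, emitters_per_sub = 40, sub_sigma_nm = 40,
                   diffuse_emitters_per_macro = 0, background_rate = 0)
  ev4 <- simulate_localizations(tr, seed = 31)
  g4 <- group_events(ev4)
  expect_equal(nrow(g4), max(ev4$true_emitter))
  expect_error(group_events(ev[2:1, ]), "sorted")
})

test_that("cell assignment matches the winding-number oracle and rejects overlap", {
  polys <- list(cbind(c(0, 1000, 1000, 0), c(0, 0, 800, 800)),
                cbind(c(1500, 2500, 2500, 1500), c(0, 0, 800, 800)),
                cbind(c(3000, 4000, 4000, 3000), c(100, 100, 900, 900)))
  set.seed(8)
  ev <- data.frame(x_nm = stats::runif(5000, -200, 4300),
                   y_nm = stats::runif(5000, -100, 1000))
  asg <- assign_cells(ev, polys)
  ref <- sapply(polys, function(p) oracle_in_polygon(ev$x_nm, ev$y_nm, p))
  expect_equal(nrow(asg), sum(rowSums(ref) == 1))
  expect_equal(asg$cell_id, apply(ref[rowSums(ref) == 1, ], 1, which),
               ignore_attr = TRUE)

  # centroid assigned, boundary inside, outside dropped
  pts <- data.frame(x_nm = c(500, 0, -50), y_nm = c(400, 400, 400))
  a2 <- assign_cells(pts, polys[1])
  expect_equal(nrow(a2), 2L)
  expect_equal(attr(a2, "n_dropped"), 1L)

  overlap <- list(polys[[1]], cbind(c(500, 1200, 1200, 500), c(0, 0, 800, 800)))
  expect_error(assign_cells(pts, overlap), "overlapping")
})

test_that("OPTICS matches the brute-force reference on random instances", {
  set.seed(13)
  for (rep in 1:8) {
    n <- 2 * sample(20:70, 1)
    minpts <- sample(c(4, 8, 16), 1)
    xy <- rbind(
      matrix(stats::rnorm(n, sd = 30), ncol = 2),
      matrix(stats::runif(n, 0, 400), ncol = 2)
    )
    eps <- sample(c(150, 1e9), 1)
    mine <- optics(xy, minpts, eps)
    ref <- oracle_optics(xy, minpts, eps)
    expect_identical(mine$order, ref$order)
    expect_equal(mine$reachability, ref$reachability, tolerance = 1e-9)
    expect_equal(mine$core_distance, ref$core_distance, tolerance = 1e-12)
  }

  # fewer points than minpts: everything undefined / unreachable
  few <- matrix(stats::runif(20), 10, 2)
  o <- optics(few, minpts = 11, epsilon_nm = 10)
  expect_true(all(is.na(o$core_distance)))
  expect_true(all(is.infinite(o$reachability)))

  # rigid motion leaves ordering and reachability unchanged
  xy <- matrix(stats::rnorm(200, sd = 50), ncol = 2)
  th <- 0.7
  rot <- xy %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rot <- sweep(rot, 2, c(1000, -500), "+")
  o1 <- optics(xy, 8, 1e9)
  o2 <- optics(rot, 8, 1e9)
  expect_identical(o1$order, o2$order)
  expect_equal(o1$reachability, o2$reachability, tolerance = 1e-9)
})

test_that("reachability cuts extract planted clusters with threshold monotonicity", {
  set.seed(5)
  blob <- function(cx, cy, n, s) cbind(stats::rnorm(n, cx, s), stats::rnorm(n, cy, s))
  xy <- rbind(blob(0, 0, 100, 10), blob(500, 0, 100, 10))
  ord <- optics(xy, minpts = 32, epsilon_nm = 3000)
  lab <- extract_clusters(ord, 50)
  expect_equal(max(lab), 2L)
  expect_true(all(lab[1:100] == lab[1]) && all(lab[101:200] == lab[101]))
  expect_false(lab[1] == lab[101])
  expect_equal(sum(lab == 0), 0L)

  # threshold above every reachability: one cluster with every core-reachable point
  big <- extract_clusters(ord, 3000)
  expect_equal(max(big), 1L)

  # monotone nesting: clusters at 35 nm sit inside single 50 nm clusters
  sub <- extract_clusters(ord, 35)
  for (s in setdiff(unique(sub), 0L)) {
    expect_equal(length(unique(lab[sub == s])), 1L)
  }

  # sparse uniform background only: all noise
  set.seed(6)
  noise <- cbind(stats::runif(100, 0, 5000), stats::runif(100, 0, 5000))
  expect_true(all(extract_clusters(optics(noise, 32, 3000), 50) == 0))
  expect_error(extract_clusters(ord, -1), "> 0")
})

test_that("nested extraction recovers the planted macro/sub structure", {
  tr <- smlm_scene(n_cells = 1)
  ev <- simulate_localizations(tr, seed = 3)
  f <- filter_events(ev)
  gr <- group_events(f)
  asg <- assign_cells(gr, tr$cells)
  ord <- optics(cbind(asg$x_nm, asg$y_nm), 32, 3000)
  nc <- nested_clusters(ord)
  st <- cluster_stats(list(cell1 = nc))
  expect_equal(nrow(st), 2L)
  expect_equal(st$n_sub, c(3L, 3L))
  expect_true(all(st$top2))
  # every sub-labeled point is macro-labeled
  expect_true(all(nc$macro[nc$sub > 0] > 0))
  # macroclusters respect the minimum size
  expect_true(all(st$n_events >= 32))

  # identical cuts give identical partitions
  same <- nested_clusters(ord, macro_nm = 50, sub_nm = 50)
  expect_identical(same$macro, same$sub)
  expect_error(nested_clusters(ord, macro_nm = 35, sub_nm = 50), "sub_nm")
})

test_that("cluster statistics select the two biggest clusters and compare conditions", {
  fake_assignment <- function(sizes, reach_means) {
    n <- sum(sizes) + 10
    macro <- rep(c(seq_along(sizes), 0L), c(sizes, 10))
    ord <- structure(list(order = seq_len(n),
                          reachability = rep(c(reach_means, 100), c(sizes, 10)),
                          core_distance = rep(10, n),
                          minpts = 32L, epsilon_nm = 3000, n = n),
                     class = "optics_ordering")
    structure(list(macro = macro, sub = macro, ordering = ord,
                   macro_nm = 50, sub_nm = 35, minpts = 32L),
              class = "cluster_assignment")
  }
  st <- cluster_stats(list(c1 = fake_assignment(c(400, 300, 50), c(10, 12, 8))))
  expect_equal(st$n_events[st$top2], c(400, 300))
  expect_false(st$top2[st$n_events == 50])

  # ties by smaller mean reachability
  st2 <- cluster_stats(list(c1 = fake_assignment(c(200, 200, 200), c(12, 8, 10))))
  top <- st2[st2$top2, ]
  expect_setequal(top$mean_reach_nm, c(8, 10))

  # Kruskal-Wallis against the hand-computed rank-sum value
  a <- st; a$n_events <- c(1, 2, 3); a$top2 <- TRUE
  b <- st; b$n_events <- c(4, 5, 6); b$top2 <- TRUE
  rep_ <- compare_conditions(a, b)
  expect_equal(rep_$chisq[rep_$metric == "n_events"],
               oracle_kruskal(1:6, rep(1:2, each = 3)), tolerance = 1e-12)
  expect_equal(rep_$df[1], 1)

  # identical samples: chi-square ~ 0, p ~ 1
  same <- compare_conditions(a, a)
  expect_lt(same$chisq[1], 1e-10)
  expect_gt(same$p[1], 0.99)
})
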