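test_that("genome generation is deterministic and respects the mean fragment length", {
  g1 <- generate_genome(10000, mean_fragment_bp = 500, seed = 1)
  g2 <- generate_genome(10000, mean_fragment_bp = 500, seed = 1)
  expect_identical(g1$fragment_boundaries, g2$fragment_boundaries)
  expect_false(identical(
    g1$fragment_boundaries,
    generate_genome(10000, mean_fragment_bp = 500, seed = 2)$fragment_boundaries
  ))

  # a mean far beyond the genome length leaves a single spanning fragment
  g3 <- generate_genome(10000, mean_fragment_bp = 100000, seed = 1)
  expect_equal(g3$n_fragments, 1L)
  expect_equal(fragment_of(g3, c(0, 5000, 9999)), c(0L, 0L, 0L))

  # 4-cutter expectation: fragment count ~ length / 256 (Poisson site counts;
  # the mean over 20 seeds has SE ~ sqrt(L/256)/sqrt(20), well within 5%)
  counts <- vapply(1:20, function(s) {
    generate_genome(3210000, mean_fragment_bp = 256, seed = s)$n_fragments
  }, numeric(1))
  expect_lt(abs(mean(counts) - 3210000 / 256) / (3210000 / 256), 0.05)

  expect_error(generate_genome(-1, mean_fragment_bp = 10), "length_bp")
  expect_error(generate_genome(100, mean_fragment_bp = 0), "mean_fragment_bp")
})

test_that("fragment and bin lookups agree with the half-open tiling", {
  g <- generate_genome(100000, mean_fragment_bp = 1000, bin_size_bp = 5000,
                       seed = 3)
  b <- g$fragment_boundaries
  expect_equal(fragment_of(g, b), seq_along(b) - 1L)     # starts map to own index
  expect_equal(fragment_of(g, 0), g$n_fragments - 1L)    # origin is in the wrap fragment
  expect_equal(bin_of(g, c(0, 4999, 5000)), c(0L, 0L, 1L))
  expect_error(bin_of(g, 100000), "outside")
})

test_that("expected contact matrix has the planted structure", {
  g <- small_genome()
  n <- g$n_bins

  # no band, no domains, no cross: a function of circular distance only
  flat <- expected_contact_matrix(g, small_truth(0, 1, 0))
  m <- flat$matrix
  for (k in c(1, 7, 40)) {
    vals <- m[cbind(1:n, (0:(n - 1) + k) %% n + 1)]
    expect_lt(diff(range(vals)), 1e-12)
  }
  expect_identical(m, t(m))
  expect_true(all(m >= 0))

  # planted band: cells on the anchor anti-diagonal exceed the
  # distance-matched off-band mean
  tr <- small_truth(2, 1, 0)
  mb <- expected_contact_matrix(g, tr)$matrix
  a <- tr$arm_anchor_bp / g$bin_size_bp
  i <- matrix(0:(n - 1), n, n); j <- t(i)
  d_anti <- abs(((i + j - 2 * a + n / 2) %% n) - n / 2) / 2
  dc <- pmin(abs(i - j), n - abs(i - j))
  sel <- dc == 30
  expect_gt(mean(mb[sel & d_anti <= 1]), mean(mb[sel & d_anti > 6]))

  expect_error(
    expected_contact_matrix(g, folding_truth(arm_anchor_bp = 9e9)),
    "anchor"
  )
})

test_that("sampled pairs reproduce the expected matrix and planted noise rates", {
  g <- small_genome()
  em <- expected_contact_matrix(g, small_truth())

  # pure informative sampling converges to the expected matrix per bin
  p <- sample_pairs(g, em, 2e5, pair_noise_model(0, 0, 1), seed = 7)
  expect_true(all(p$true_label == "informative"))
  p$label <- "informative"
  raw <- bin_contacts(p, g)
  expect_gt(stats::cor(as.vector(raw$matrix), as.vector(em$matrix)), 0.95)

  # planted noise class frequency is binomial around the requested fraction
  p2 <- sample_pairs(g, em, 1e5, pair_noise_model(0.05, 0.2, 3), seed = 8)
  n_uncut <- sum(p2$true_label == "uncut")
  expect_lt(abs(n_uncut - 2e4), 3 * sqrt(1e5 * 0.2 * 0.8))
  # all planted self-circles sit on one fragment with outward strands
  sc <- p2[p2$true_label == "self_circle", ]
  expect_true(all(sc$frag1 == sc$frag2))
  expect_true(all(sc$strand1 == "-" & sc$strand2 == "+"))

  # determinism and error paths
  expect_identical(sample_pairs(g, em, 1000, seed = 9),
                   sample_pairs(g, em, 1000, seed = 9))
  expect_error(pair_noise_model(0.6, 0.5), "sum")
})

test_that("simulated localizations carry truth labels and the planted footprint", {
  # single subcluster, no envelope, no background: every event truth-labeled
  poly <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  tr <- smlm_truth(list(poly), list(matrix(c(500, 500), 1)),
                   list(list(matrix(c(500, 500), 1))),
                   emitters_per_sub = 200, sub_sigma_nm = 12,
                   diffuse_emitters_per_macro = 0, background_rate = 0)
  ev <- simulate_localizations(tr, seed = 11)
  expect_true(all(ev$true_sub == 1))
  expect_true(all(ev$true_cell == 1))

  # event coordinate spread ~ subcluster footprint (jitter adds ~5%)
  expect_lt(abs(stats::sd(ev$x_nm) - 12) / 12, 0.10)
  expect_lt(abs(stats::sd(ev$y_nm) - 12) / 12, 0.10)

  # blink runs are consecutive frames of the same emitter
  runs <- split(ev$frame, ev$true_emitter)
  expect_true(all(vapply(runs, function(f) {
    length(f) <= 3 && all(diff(sort(f)) == 1)
  }, logical(1))))

  expect_identical(simulate_localizations(tr, seed = 4),
                   simulate_localizations(tr, seed = 4))
  expect_error(smlm_truth(list(), list(), list()), "empty cell list")
  # centers outside the cell polygon are rejected
  expect_error(
    smlm_truth(list(poly), list(matrix(c(500, 500), 1)),
               list(list(matrix(c(5000, 5000), 1)))),
    "outside"
  )
})

test_that("pairs and localization text round-trips preserve the tables", {
  g <- generate_genome(100000, mean_fragment_bp = 500, bin_size_bp = 5000,
                       seed = 2)
  em <- expected_contact_matrix(g, folding_truth(arm_anchor_bp = 50000,
                                                 cid_boundaries_bp = c(30000, 70000)))
  p <- sample_pairs(g, em, 500, seed = 1)
  f <- withr::local_tempfile(fileext = ".pairs")
  write_pairs(p, f)
  expect_equal(read_pairs(f), p)

  tr <- smlm_scene(n_cells = 1, emitters_per_sub = 10,
                   diffuse_emitters_per_macro = 0)
  ev <- simulate_localizations(tr, seed = 2)
  fl <- withr::local_tempfile(fileext = ".csv")
  write_localizations(ev[, 1:6], fl)
  expect_equal(read_localizations(fl), ev[, 1:6], tolerance = 1e-12)

  fw <- withr::local_tempfile(fileext = ".wkt")
  write_polygons_wkt(tr$cells, fw)
  polys <- read_polygons_wkt(fw)
  expect_equal(polys[[1]], tr$cells[[1]], tolerance = 1e-6, ignore_attr = TRUE)
})
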