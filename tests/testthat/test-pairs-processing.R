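make_pairs <- function(pos1, pos2, s1, s2, g) {
  data.frame(read_id = sprintf("r%d", seq_along(pos1)), chr1 = "chr",
             pos1 = pos1, chr2 = "chr", pos2 = pos2,
             strand1 = s1, strand2 = s2,
             frag1 = fragment_of(g, pos1), frag2 = fragment_of(g, pos2),
             stringsAsFactors = FALSE)
}

test_that("orientation profile counts configurations by circular fragment separation", {
  g <- generate_genome(100000, mean_fragment_bp = 1000, bin_size_bp = 5000,
                       seed = 5)
  b <- g$fragment_boundaries
  # all pairs inward-facing at separation 1
  p <- make_pairs(b[1:10] + 1, b[2:11] + 1, "+", "-", g)
  prof <- orientation_profile(p, g, 5)
  expect_equal(unname(prof$freq["1", ]), c(0, 1, 0, 0))
  expect_equal(unname(prof$n[["1"]]), 10)
  expect_true(all(is.na(prof$freq["3", ])))

  # equal random strands: every populated separation is ~uniform over classes
  g2 <- small_genome()
  em <- expected_contact_matrix(g2, small_truth())
  pr <- sample_pairs(g2, em, 5e4, pair_noise_model(0, 0, 1), seed = 3)
  prof2 <- orientation_profile(pr, g2, 30)
  pop <- prof2$n >= 200
  for (cls in colnames(prof2$freq)) {
    f <- prof2$freq[pop, cls]
    n <- prof2$n[pop]
    expect_true(all(abs(f - 0.25) < 3 * sqrt(0.25 * 0.75 / n) + 0.02))
  }

  # k_max = 0 keeps only the same-fragment row
  prof0 <- orientation_profile(p, g, 0)
  expect_equal(nrow(prof0$freq), 1L)
  expect_error(orientation_profile(p[0, ], g, 5), "empty")
})

test_that("event thresholds track the planted orientation excess", {
  g <- generate_genome(2000000, mean_fragment_bp = 256, bin_size_bp = 5000,
                       seed = 2)
  em <- expected_contact_matrix(
    g, folding_truth(arm_anchor_bp = 1.8e6,
                     cid_boundaries_bp = c(0.5e6, 1.2e6))
  )
  # planted (+,-) excess up to 3 fragments, none beyond
  p <- sample_pairs(g, em, 1e5, pair_noise_model(0.05, 0.15, 3), seed = 4)
  thr <- estimate_event_thresholds(orientation_profile(p, g, 50))
  expect_equal(thr$k_uncut, 3L)
  expect_equal(thr$k_circle, 0L) # planted self-circles are same-fragment only

  # planted excess reaching only 1 fragment
  p1 <- sample_pairs(g, em, 1e5, pair_noise_model(0.02, 0.15, 1), seed = 5)
  thr1 <- estimate_event_thresholds(orientation_profile(p1, g, 50))
  expect_equal(thr1$k_uncut, 1L)

  # no planted noise: converged everywhere, thresholds 0
  p0 <- sample_pairs(g, em, 5e4, pair_noise_model(0, 0, 1), seed = 6)
  thr0 <- estimate_event_thresholds(orientation_profile(p0, g, 50))
  expect_equal(unlist(thr0, use.names = FALSE), c(0L, 0L))
})

test_that("classification follows orientation, separation and the same-fragment rule", {
  g <- generate_genome(100000, mean_fragment_bp = 1000, bin_size_bp = 5000,
                       seed = 5)
  b <- g$fragment_boundaries
  # same fragment, outward strands: discarded as same_fragment (the
  # self-circle geometry lives on a single fragment)
  p <- make_pairs(b[5] + 1, b[5] + 5, "-", "+", g)
  expect_equal(classify_pairs(p, g, 3, 3)$label, "same_fragment")

  # far separation is informative whatever the orientation
  far <- make_pairs(rep(b[1] + 1, 4), rep(b[60] + 1, 4),
                    c("+", "+", "-", "-"), c("+", "-", "+", "-"), g)
  expect_true(all(classify_pairs(far, g, 3, 3)$label == "informative"))

  # near separation: only the class-specific orientation is removed
  near <- make_pairs(rep(b[5] + 1, 4), rep(b[7] + 1, 4),
                     c("+", "+", "-", "-"), c("+", "-", "+", "-"), g)
  expect_equal(classify_pairs(near, g, 3, 3)$label,
               c("informative", "uncut", "self_circle", "informative"))
  # thresholds (0,0): nothing near-diagonal is removed
  expect_true(all(classify_pairs(near, g, 0, 0)$label == "informative"))

  # permutation equivariance
  g2 <- small_genome()
  em <- expected_contact_matrix(g2, small_truth())
  pr <- sample_pairs(g2, em, 2000, seed = 9)
  lab <- classify_pairs(pr, g2, 3, 0)$label
  perm <- sample(nrow(pr))
  expect_identical(classify_pairs(pr[perm, ], g2, 3, 0)$label, lab[perm])

  expect_error(classify_pairs(pr[, -6], g2, 1, 1), "lacks column")
})

test_that("generator-labeled pairs are recovered at >= 99% and noise removal restores the map", {
  g <- small_genome()
  em <- expected_contact_matrix(g, small_truth())
  p <- sample_pairs(g, em, 1e5, pair_noise_model(0.05, 0.10, 3), seed = 2)
  thr <- estimate_event_thresholds(orientation_profile(p, g, 50))
  lab <- classify_pairs(p, g, thr$k_uncut, thr$k_circle)

  # truth convention: same-fragment events (all planted self-circles, plus
  # informative ligations landing on one fragment) are correctly discarded
  eff <- lab$true_label
  eff[eff == "self_circle"] <- "same_fragment"
  eff[eff == "informative" & lab$frag1 == lab$frag2] <- "same_fragment"
  expect_gt(mean(lab$label == eff), 0.99)
  # disagreements confined to separations at or below the threshold
  dis <- lab$label != eff
  sep <- pmin(abs(lab$frag1 - lab$frag2),
              g$n_fragments - abs(lab$frag1 - lab$frag2))
  expect_true(all(sep[dis] <= max(thr$k_uncut, thr$k_circle)))

  # the classified map matches the truth-labeled map
  map_called <- bin_contacts(lab, g)
  truth_lab <- lab
  truth_lab$label <- ifelse(eff == "informative", "informative", "drop")
  map_truth <- bin_contacts(truth_lab, g)
  expect_gt(stats::cor(as.vector(map_called$matrix),
                       as.vector(map_truth$matrix)), 0.99)
})

test_that("binning accumulates symmetric counts with the documented mass", {
  g <- generate_genome(100000, mean_fragment_bp = 500, bin_size_bp = 5000,
                       seed = 2)
  p <- make_pairs(c(1000, 1000), c(12000, 12000), "+", "-", g)
  p$label <- "informative"
  m <- bin_contacts(p, g)$matrix
  expect_equal(m[1, 3], 2)
  expect_equal(m[3, 1], 2)
  expect_equal(sum(m), 4)

  # no informative pairs: all-zero map of the right shape
  p$label <- "uncut"
  expect_equal(sum(bin_contacts(p, g)$matrix), 0)
  expect_equal(dim(bin_contacts(p, g)$matrix), c(20, 20))

  # counting identity on random pairs
  em <- expected_contact_matrix(g, folding_truth(arm_anchor_bp = 50000,
                                                 cid_boundaries_bp = c(30000, 70000)))
  pr <- sample_pairs(g, em, 1e4, pair_noise_model(0, 0, 1), seed = 3)
  pr$label <- "informative"
  mm <- bin_contacts(pr, g)$matrix
  diag_pairs <- sum(pr$pos1 %/% 5000 == pr$pos2 %/% 5000)
  expect_equal(sum(mm), 2 * (1e4 - diag_pairs) + diag_pairs)

  expect_error(bin_contacts(pr, g, 0), "bin_size")
  pr$label <- NULL
  expect_error(bin_contacts(pr, g), "classified")
})
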