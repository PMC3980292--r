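# Odour feature extraction, clustering and the Mantel test.

test_that("features are window maxima between consecutive onsets", {
  proto <- generate_protocol(c("a", "b"), interstimulus_frames = 10, seed = 1)
  T <- matrix(0, 20, 1)
  T[4, 1] <- 4.2                               # inside the first window
  F <- extract_features(T, proto)
  expect_equal(dim(F$values), c(2L, 1L))
  expect_equal(F$values[1, 1], 4.2)
  expect_equal(F$values[2, 1], 0)

  # flat trace gives all-zero features; outside-window activity is ignored
  T2 <- matrix(0, 20, 2)
  F2 <- extract_features(T2, proto)
  expect_true(all(F2$values == 0))
  T3 <- T; T3[15, 1] <- 9                      # second window only
  F3 <- extract_features(T3, proto)
  expect_equal(F3$values[1, 1], 4.2)
  expect_equal(F3$values[2, 1], 9)

  # pre-onset baseline subtraction
  T4 <- matrix(1, 20, 1); T4[12, 1] <- 3
  F4 <- extract_features(T4, proto, baseline_mode = "pre_onset")
  expect_equal(F4$values[2, 1], 2)             # 3 minus baseline 1
  expect_error(extract_features(matrix(0, 5, 1), proto), "cover")
})

test_that("recovered features match ground-truth response amplitudes", {
  # transient kernel is truncated at 15 s (75 frames at 5 Hz); 90-frame
  # spacing guarantees windows see only their own stimulus
  proto <- generate_protocol(sprintf("o%d", 1:6), interstimulus_frames = 90,
                             frame_rate = 5, seed = 4)
  truth <- generate_ground_truth(c(30, 30), 3, proto, radius_range = c(3, 4),
                                 noise_sigma = 0, seed = 6, n_artifacts = 0,
                                 spontaneous_amplitude = 0)
  F <- extract_features(truth$traces, proto)
  amp <- truth$response_amplitudes[, proto$label]   # units x stimuli
  expect_equal(F$values, t(amp), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Euclidean distances match a brute-force double loop", {
  F <- structure(list(values = rbind(c(0, 0), c(3, 4), c(1, 1)),
                      stimulus_labels = c("x", "y", "z"),
                      unit_ids = c("1", "2")), class = "feature_matrix")
  D <- euclidean_distances(F)
  expect_equal(D$d[1, 2], 5)
  expect_equal(diag(D$d), rep(0, 3))
  expect_equal(D$d, t(D$d), tolerance = 1e-12)

  V <- with_seed(13, matrix(rnorm(8 * 5), 8, 5))
  D2 <- euclidean_distances(V)$d
  ref <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) ref[i, j] <- sqrt(sum((V[i, ] - V[j, ])^2))
  expect_equal(D2, ref, tolerance = 1e-12)
})

test_that("Ward clustering joins the closest structure first", {
  # two tight, far-apart pairs merge internally before anything else
  X <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  rownames(X) <- c("a1", "a2", "b1", "b2")
  hc <- ward_cluster(X)
  expect_true(all(hc$merge[1, ] < 0))
  expect_true(all(hc$merge[2, ] < 0))
  expect_true(all(diff(hc$height) >= -1e-12))  # monotone heights

  # collinear points 0, 1, 10: first merge joins {0, 1}
  Y <- matrix(c(0, 1, 10), ncol = 1)
  hc2 <- ward_cluster(Y)
  expect_setequal(hc2$merge[1, ], c(-1L, -2L))

  # pure-subtree detection
  labs <- c("ref", "x", "ref", "y")
  Z <- rbind(c(0, 0), c(5, 5), c(0.2, 0), c(-4, 6))
  rownames(Z) <- labs
  hcz <- ward_cluster(Z)
  expect_true(is_pure_subtree(hcz, "ref"))
  # replicates split across distant clusters are not a pure subtree
  W <- rbind(c(0, 0), c(0.1, 0), c(9, 9), c(9.1, 9))
  rownames(W) <- c("ref", "x", "ref", "y")
  expect_false(is_pure_subtree(ward_cluster(W), "ref"))

  skip_if_not_installed("ape")
  nwk <- export_newick(hcz)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "ref")
})

test_that("Mantel test: exact self-correlation and seeded determinism", {
  D <- euclidean_distances(with_seed(5, matrix(rnorm(10 * 3), 10, 3)))
  r <- mantel_test(D, D, n_permutations = 99, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 100)
  r2 <- mantel_test(D, D, n_permutations = 99, seed = 1)
  expect_identical(r, r2)
  expect_error(mantel_test(D$d, D$d[1:5, 1:5]), "size")

  # statistic agrees with the vegan implementation
  skip_if_not_installed("vegan")
  D2 <- euclidean_distances(with_seed(6, matrix(rnorm(10 * 3), 10, 3)))
  vg <- vegan::mantel(stats::as.dist(D$d), stats::as.dist(D2$d),
                      permutations = 0)
  expect_equal(mantel_test(D, D2, 9, seed = 0)$r, unname(vg$statistic),
               tolerance = 1e-12)
})

test_that("Mantel p-values are calibrated under the null", {
  # feature matrices independent of each other: p should be ~Uniform(0,1)
  ps <- with_seed(99, vapply(1:200, function(b) {
    F1 <- matrix(rnorm(9 * 4), 9, 4)
    F2 <- matrix(rnorm(9 * 4), 9, 4)
    mantel_test(euclidean_distances(F1), euclidean_distances(F2),
                n_permutations = 199, seed = b)$p
  }, numeric(1)))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))  # discrete p -> ties
  expect_gt(ks$p.value, 0.01)
})

test_that("Mantel p is invariant to a common relabelling of both matrices", {
  F1 <- with_seed(7, matrix(rnorm(8 * 3), 8, 3))
  F2 <- with_seed(8, matrix(rnorm(8 * 3), 8, 3))
  D1 <- euclidean_distances(F1)$d; D2 <- euclidean_distances(F2)$d
  perm <- with_seed(9, sample.int(8))
  r1 <- mantel_test(D1, D2, 499, seed = 3)
  r2 <- mantel_test(D1[perm, perm], D2[perm, perm], 499, seed = 3)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_lt(abs(r1$p - r2$p), 0.1)     # same null distribution, finite perms
})
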