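# Unit maps built from coefficient images.

test_that("indicator rows reproduce their supports; ties go to the lower row", {
  n <- 25
  S <- rbind(c(rep(1, 10), rep(0, 15)),
             c(rep(0, 10), rep(1, 10), rep(0, 5)))
  m <- build_map(S, c(5, 5), threshold_mode = "absolute", threshold = 0.5)
  expect_equal(m$labels[1:10], rep(1L, 10))
  expect_equal(m$labels[11:20], rep(2L, 10))
  expect_equal(m$labels[21:25], rep(0L, 5))

  # equal coefficients in two rows: lower row index wins
  S2 <- rbind(c(1, 0.6), c(1, 0))
  m2 <- build_map(S2, c(1, 2), threshold_mode = "absolute", threshold = 0.1)
  expect_equal(m2$labels[1], 1L)
})

test_that("labelling is invariant to positive rescaling of a single row", {
  S <- with_seed(9, matrix(abs(rnorm(4 * 60)), 4, 60))
  for (mode in c("relative", "quantile")) {
    m1 <- build_map(S, c(6, 10), threshold_mode = mode, threshold = 0.5)
    S2 <- S; S2[3, ] <- 17.3 * S2[3, ]
    m2 <- build_map(S2, c(6, 10), threshold_mode = mode, threshold = 0.5)
    expect_identical(m1$labels, m2$labels)
  }
  expect_error(build_map(S, c(6, 10), threshold_mode = "nope"))
})

test_that("map regions track true footprints on clean synthetic data", {
  truth <- small_truth(shape = c(40, 40), n_units = 4, noise_sigma = 0.05,
                       seed = 33)
  A <- render_movie(truth)
  A <- A[rep(seq_len(nrow(A)), 3), ]
  run <- run_stream(A, shape = c(40, 40), k = 8, c = 4, filter_width = 1,
                    select_every = 10)
  map <- build_map(run$model$S, c(40, 40))
  jac <- map_truth_jaccard(map, run$model, truth)
  expect_gte(median(jac), 0.6)
  # labelled pixels carry positive confidence
  expect_true(all(map$confidence[map$labels > 0] > 0))
})

test_that("completeness timeline is reported per snapshot", {
  truth <- small_truth(shape = c(30, 30), n_units = 3, noise_sigma = 0.1,
                       seed = 41)
  A <- render_movie(truth)
  A <- A[rep(seq_len(nrow(A)), 3), ]
  run <- run_stream(A, shape = c(30, 30), k = 6, c = 4, filter_width = 1,
                    select_every = 30, snapshot_every = 60)
  comp <- map_completeness(run, truth)
  expect_true(all(comp$completeness >= 0 & comp$completeness <= 1))
  expect_equal(tail(comp$frame, 1), nrow(A))
  # snapshot interval longer than the stream: single final snapshot
  run1 <- run_stream(A, shape = c(30, 30), k = 6, c = 4, filter_width = 1,
                     snapshot_every = 10 * nrow(A))
  expect_equal(unique(map_completeness(run1, truth)$frame), nrow(A))

  # map snapshots carry their stream time
  run2 <- run_stream(A, shape = c(30, 30), k = 6, c = 4, filter_width = 1,
                     snapshot_every = 60, snapshot_maps = TRUE,
                     compute_recon = FALSE)
  tl <- map_timeline(run2, truth)
  expect_gt(length(tl$maps), 1L)
  expect_equal(tl$maps[[1]]$frame_index, 60L)
  expect_s3_class(tl$maps[[1]], "unit_map")
  expect_equal(nrow(tl$completeness), length(tl$maps))
  expect_error(map_timeline(run1), "snapshot")
})

test_that("map rendering is deterministic with pairwise-distinct colours", {
  S <- diag(100)[, rep(1:100, each = 2)]
  map <- build_map(S, c(10, 20), threshold_mode = "absolute", threshold = 0.5)
  r1 <- render_map(map, palette_seed = 4)
  r2 <- render_map(map, palette_seed = 4)
  expect_identical(r1, r2)
  expect_equal(anyDuplicated(r1$legend$colour), 0L)
  expect_equal(nrow(r1$legend), 100L)

  # 2-unit map: background black plus two distinct colours
  S2 <- rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0))
  m2 <- build_map(S2, c(2, 3), threshold_mode = "absolute", threshold = 0.5)
  rg <- render_map(m2)
  cols <- apply(matrix(aperm(rg$rgb, c(3, 1, 2)), nrow = 3), 2,
                paste, collapse = ",")
  expect_equal(length(unique(cols)), 3L)
  expect_true("0,0,0" %in% cols)
})

test_that("maps survive the disk round trip", {
  S <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 0))
  map <- build_map(S, c(2, 2), threshold_mode = "absolute", threshold = 0.5)
  stem <- file.path(withr::local_tempdir(), "map")
  write_map(map, stem)
  expect_true(all(file.exists(paste0(stem, c(".png", ".csv", "_labels.tif",
                                             "_legend.csv")))))
  df <- read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(df), 3L)
  expect_equal(df$unit, map$labels[map$labels > 0])
})
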