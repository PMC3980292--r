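# CCIPCA subspace maintenance, convex-cone selection and the per-frame loop.

principal_angle_deg <- function(a, b) {
  qa <- qr.Q(qr(as.matrix(a))); qb <- qr.Q(qr(as.matrix(b)))
  s <- svd(crossprod(qa, qb))$d
  max(acos(pmin(1, s)) * 180 / pi)
}

test_that("CCIPCA fixed point: a repeated frame keeps the component collinear", {
  v <- c(3, 0, 4, 0, 0) / 5
  V <- pc_matrix_new(5, 1)
  for (i in 1:50) {
    V <- update_ipca(V, 2 * v)
    vhat <- V$components[, 1] / sqrt(sum(V$components[, 1]^2))
    expect_lt(sqrt(sum((vhat - v)^2)), 1e-12)
  }
  expect_equal(V$frames_seen, 50L)
})

test_that("CCIPCA converges to the batch eigendecomposition", {
  # zero-mean stream with covariance diag(9, 4, 1)
  X <- with_seed(0, cbind(rnorm(5000, sd = 3), rnorm(5000, sd = 2),
                          rnorm(5000, sd = 1)))
  V <- pc_matrix_new(3, 3)
  for (i in 1:5000) V <- update_ipca(V, X[i, ])
  e <- eigen(crossprod(X) / 5000, symmetric = TRUE)   # batch oracle
  expect_lt(principal_angle_deg(V$components[, 1], e$vectors[, 1]), 5)
  # component norms approach the eigenvalues
  norms <- sqrt(colSums(V$components^2))
  expect_equal(norms, e$values, tolerance = 0.15)
  # near-orthogonality after convergence
  Vn <- sweep(V$components, 2, norms, "/")
  G <- crossprod(Vn) - diag(3)
  expect_lt(max(abs(G)), 0.1)
})

test_that("update_ipca leaves its inputs untouched and seeds deterministically", {
  X <- with_seed(4, matrix(rnorm(40), 10, 4))
  V0 <- pc_matrix_new(4, 3)
  V1 <- update_ipca(V0, X[1, ])
  expect_identical(V0$components, matrix(0, 4, 3))
  expect_equal(V1$seeded, 1L)
  expect_equal(V1$components[, 1], X[1, ])       # first seed = first frame
  V2 <- update_ipca(V1, X[2, ])
  # second seed is the residual after Gram-Schmidt against component 1
  v1 <- V2$components[, 1] / sqrt(sum(V2$components[, 1]^2))
  expect_lt(abs(sum(V2$components[, 2] * v1)), 1e-10)
  # an all-zero frame neither seeds nor corrupts
  V3 <- update_ipca(V2, rep(0, 4))
  expect_equal(V3$seeded, V2$seeded)
  expect_true(all(is.finite(V3$components)))
})

test_that("convex cone reproduces the hand-computed projection sequence", {
  M <- cbind(c(2, 0), c(0, 1), c(1, 1))
  r <- convex_cone(M, 2)
  # first pick: column 1 (norm 2); after downdating, columns 2 and 3 both
  # have residual norm 1, tie broken by lowest index -> column 2
  expect_equal(r$selected, c(1L, 2L))
  expect_equal(r$basis, cbind(c(1, 0), c(0, 1)))
  expect_equal(r$S, rbind(c(2, 0, 1), c(0, 1, 1)))

  # c = 1 picks the max-norm column
  expect_equal(convex_cone(M, 1)$selected, 1L)
  M2 <- cbind(c(1, 0), c(0, 5))
  expect_equal(convex_cone(M2, 1)$selected, 2L)
})

test_that("convex cone basis is orthonormal and residual norms decrease", {
  M <- with_seed(8, matrix(rnorm(20 * 100), 20, 100))
  r <- convex_cone(M, 10)
  expect_lt(max(abs(crossprod(r$basis) - diag(10))), 1e-10)
  expect_true(all(diff(r$max_residual_norm) <= 1e-9))
  expect_equal(r$S, crossprod(r$basis, M), tolerance = 1e-10)
})

test_that("convex cone recovers pure pixels of noiseless mixtures exactly", {
  for (seed in c(11, 12, 13)) {
    cm <- conical_mixture(c_true = 5, n_mixed = 60, seed = seed)
    r <- convex_cone(cm$A, 5)
    expect_setequal(r$selected, cm$pure)
    # T * S reconstructs the mixture to numerical precision
    rec <- r$basis %*% r$S
    expect_lt(norm(rec - cm$A, "F") / norm(cm$A, "F"), 1e-10)
  }
})

test_that("degenerate inputs truncate the selection with a warning", {
  M <- cbind(c(1, 0), c(2, 0), c(3, 0))     # rank 1
  expect_warning(r <- convex_cone(M, 2), "selectable")
  expect_equal(r$selected, 3L)
  expect_false(r$complete)
  expect_error(convex_cone(M, 2, on_short = "error"), "selectable")
})

test_that("compute_S projects, clips and refits non-negatively", {
  # basis e1: S row equals the first row of A
  A <- with_seed(2, matrix(rnorm(12), 3, 4))
  e1 <- c(1, 0, 0)
  expect_equal(compute_S(A, cbind(e1)), A[1, , drop = FALSE],
               ignore_attr = TRUE)
  # orthonormal basis spanning the column space reconstructs A exactly
  B <- qr.Q(qr(with_seed(3, matrix(rnorm(9), 3, 3))))
  S <- compute_S(A, B)
  expect_lt(max(abs(B %*% S - A)), 1e-10)
  # clipping contract
  Sc <- compute_S(A, B, nonneg = TRUE)
  expect_gte(min(Sc), 0)
  # per-pixel NNLS satisfies the KKT conditions
  Sn <- compute_S(A, B, nonneg = TRUE, method = "nnls")
  for (j in seq_len(ncol(A))) {
    g <- crossprod(B, A[, j] - B %*% Sn[, j])    # gradient of 0.5||.||^2
    expect_true(all(g <= 1e-8))                  # no ascent direction left
    expect_true(all(abs(g[Sn[, j] > 0]) < 1e-8)) # active coords at optimum
  }
})

test_that("reconstruction is an orthogonal projection", {
  S <- with_seed(6, matrix(rnorm(3 * 20), 3, 20))
  inspan <- as.numeric(crossprod(S, c(1, -2, 0.5)))
  r <- reconstruct(inspan, S)
  expect_equal(r$frame_hat, inspan, tolerance = 1e-10)
  expect_lt(r$residual_norm, 1e-9)

  # orthogonal complement maps to zero
  v <- with_seed(7, rnorm(20))
  perp <- v - reconstruct(v, S)$frame_hat
  expect_lt(sqrt(sum(reconstruct(perp, S)$frame_hat^2)), 1e-9)

  # contraction and idempotence for arbitrary frames
  expect_lte(sqrt(sum(reconstruct(v, S)$frame_hat^2)), sqrt(sum(v^2)))
  h <- reconstruct(v, S)$frame_hat
  expect_equal(reconstruct(h, S)$frame_hat, h, tolerance = 1e-10)

  # duplicated rows (rank deficiency) are tolerated
  Sdup <- rbind(S, S[1, ])
  expect_equal(reconstruct(v, Sdup)$frame_hat, reconstruct(v, S)$frame_hat,
               tolerance = 1e-9)
})

test_that("per-frame loop: warmup guard, residual decay, determinism", {
  truth <- small_truth(shape = c(36, 36), n_units = 5, seed = 21,
                       spontaneous_amplitude = 0.3)
  A <- render_movie(truth)
  # stationary noiseless 5-source stream: repeat the movie to 500 frames
  A <- A[rep(seq_len(nrow(A)), length.out = 500), ]

  st <- new_stream(c(36, 36), k = 10, c = 5, filter_width = 1)
  r1 <- process_frame(st, A[1, ])
  expect_true(r1$is_warmup)
  expect_equal(r1$frame_hat, A[1, ])            # frame passes unmodified
  r2 <- process_frame(st, A[2, ])
  expect_true(r2$is_warmup)
  for (i in 3:500) res <- process_frame(st, A[i, ])
  expect_false(res$is_warmup)
  expect_lt(res$residual_norm / sqrt(sum(res$frame^2)), 0.05)

  # bit-identical factor model on a re-run (no hidden randomness)
  run1 <- run_stream(A, shape = c(36, 36), k = 10, c = 5, filter_width = 1)
  run2 <- run_stream(A, shape = c(36, 36), k = 10, c = 5, filter_width = 1)
  expect_identical(run1$model, run2$model)
})

test_that("selection thinning leaves the final model unchanged", {
  truth <- small_truth(shape = c(32, 32), n_units = 4, noise_sigma = 0.1,
                       seed = 14)
  A <- render_movie(truth)
  r1 <- run_stream(A, k = 8, c = 6, filter_width = 3, select_every = 1)
  r7 <- run_stream(A, k = 8, c = 6, filter_width = 3, select_every = 7)
  expect_identical(r1$model$selected, r7$model$selected)
  expect_equal(r1$model$S, r7$model$S, tolerance = 1e-12)
  expect_equal(r1$model$T, r7$model$T, tolerance = 1e-12)
})

test_that("streaming recovers well-separated units and matches batch", {
  proto <- small_protocol(n_labels = 10, isi = 30)
  truth <- generate_ground_truth(c(40, 40), 5, proto, radius_range = c(3, 5),
                                 noise_sigma = 0.1, seed = 3, n_artifacts = 2)
  A <- render_movie(truth)
  A <- A[rep(seq_len(nrow(A)), 3), ]           # 900 frames, stationary
  run <- run_stream(A, shape = c(40, 40), k = 10, c = 7, filter_width = 3,
                    select_every = 5)
  expect_true(all(units_hit(run$model$selected, truth)))
  bt <- batch_pipeline(A, 10, 7, filter_width = 3, shape = c(40, 40))
  expect_true(all(units_hit(bt$model$selected, truth)))
  rep_ <- compare_models(run$model, bt$model, truth, match_radius = 4)
  expect_gte(rep_$hit_fraction, 0.8)
})
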