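# The streaming factorisation core: CCIPCA subspace maintenance, greedy
# convex-cone extreme-column selection, and the combined per-frame update
# loop that produces the basis time series T, the coefficient images S and a
# per-frame low-rank reconstruction.

#' New incremental principal-component state
#'
#' Component estimates are stored as the *columns* of an `n x k` matrix
#' (pixels x components); rows of the conceptual k x n component matrix are
#' available via [pc_components()]. Components are initialised from the first
#' k incoming frames after Gram-Schmidt against already-seeded components
#' (deterministic, data-driven); frames whose residual is degenerate do not
#' seed a component.
#'
#' @param n number of pixels.
#' @param k number of components to maintain.
#' @param tol numeric tolerance below which a vector counts as degenerate.
#' @return object of class `pc_matrix`.
#' @export
pc_matrix_new <- function(n, k, tol = 1e-12) {
  stopifnot(k >= 1, n >= 1)
  structure(list(components = matrix(0, n, k), k = as.integer(k),
                 n = as.integer(n), seeded = 0L, frames_seen = 0L, tol = tol),
            class = "pc_matrix")
}

#' Component matrix of a `pc_matrix` (k x n, components in rows)
#' @param V a `pc_matrix`.
#' @export
pc_components <- function(V) t(V$components)

#' CCIPCA single-frame update
#'
#' Candid covariance-free incremental PCA: for components r = 1..k in order,
#' the estimate v_r is updated as
#' `v_r <- ((i-1)/i) v_r + (1/i) x (x' v_r / ||v_r||)`
#' with i the number of frames seen, after which the working copy of the
#' frame is downdated by its projection onto the unit-normalised updated v_r,
#' so the next component sees the residual. The amortised 1/i weights contain
#' no forgetting factor; component norms converge to the covariance
#' eigenvalues and directions to the eigenvectors on stationary streams. The
#' input frame is never modified; a component whose norm collapses is
#' re-seeded from the current residual rather than dividing by zero.
#'
#' @param V a [pc_matrix_new()] state.
#' @param frame normalised frame vector (length n).
#' @param amnesic forgetting parameter (0 = plain 1/i running average;
#'   positive values give higher weight to recent time points, useful when
#'   the scene drifts, e.g. slow movement of the animal).
#' @return the updated `pc_matrix` (input untouched).
#' @export
update_ipca <- function(V, frame, amnesic = 0) {
  stopifnot(inherits(V, "pc_matrix"), length(frame) == V$n)
  comp <- V$components + 0                       # unshared copy for in-place C++
  i <- V$frames_seen + 1L
  seeded <- ccipca_update_inplace(comp, V$seeded, as.numeric(frame), i, V$tol,
                                  amnesic)
  structure(list(components = comp, k = V$k, n = V$n, seeded = seeded,
                 frames_seen = i, tol = V$tol), class = "pc_matrix")
}

#' Greedy convex-cone extreme-column selection
#'
#' Repeats c times: pick the column of largest Euclidean norm (ties -> lowest
#' index), append its unit-normalised version to the basis, record the
#' projection coefficients of all columns onto it as a row of S, and subtract
#' that projection from every column. Because each pick is orthogonal to all
#' previous basis vectors, the returned basis is orthonormal and
#' `S = t(basis) %*% M`. On a noiseless non-negative mixture that contains
#' pure columns, the picks are exactly the pure (extreme) columns — the
#' minimal generators of the convex cone spanned by the data.
#'
#' @param M matrix whose columns are the candidates (e.g. k x n component
#'   summary, columns = pixels; or the movie itself, columns = pixel series).
#' @param c number of columns to select.
#' @param tol_rel columns with residual norm below `tol_rel` times the
#'   initial maximum norm are ineligible.
#' @param on_short `"warn"` (return fewer columns with `complete = FALSE`) or
#'   `"error"` when fewer than `c` eligible columns remain.
#' @return list: `selected` (1-based column indices), `basis` (orthonormal
#'   columns), `S` (projection coefficient rows), `max_residual_norm`
#'   (non-increasing across iterations), `complete`.
#' @export
convex_cone <- function(M, c, tol_rel = 1e-9, on_short = c("warn", "error")) {
  on_short <- match.arg(on_short)
  stopifnot(c >= 1)
  res <- convex_cone_cpp(as.matrix(M), as.integer(c), tol_rel)
  if (!res$complete) {
    msg <- sprintf("convex cone: only %d of %d columns selectable above tolerance",
                   length(res$selected), c)
    if (on_short == "error") stop(msg) else warning(msg)
    res$basis <- res$basis[, seq_along(res$selected), drop = FALSE]
    res$S <- res$S[seq_along(res$selected), , drop = FALSE]
    res$max_residual_norm <- res$max_residual_norm[seq_along(res$selected)]
  }
  res
}

#' Coefficient images for a given basis
#'
#' `S = t(T_basis) %*% A`: per-pixel projection coefficients onto the
#' (unit-normalised) basis columns. With `nonneg = TRUE`, negative entries
#' are either clipped at zero (default, streaming-safe) or each pixel is
#' refit by non-negative least squares (`method = "nnls"`, offline option).
#'
#' @param A matrix with pixels in columns (same row dimension as the basis).
#' @param T_basis matrix with unit-normalised basis vectors in columns.
#' @param nonneg enforce non-negativity of S.
#' @param method `"clip"` or `"nnls"`.
#' @export
compute_S <- function(A, T_basis, nonneg = FALSE, method = c("clip", "nnls")) {
  method <- match.arg(method)
  if (nrow(A) != nrow(T_basis)) stop("dimension mismatch between A and basis")
  if (nonneg && method == "nnls") {
    S <- apply(A, 2, function(y) nnls_solve(T_basis, y))
    if (is.null(dim(S))) S <- matrix(S, nrow = ncol(T_basis))
    return(S)
  }
  S <- crossprod(T_basis, A)
  if (nonneg) S[S < 0] <- 0
  S
}

# Lawson-Hanson active-set non-negative least squares: min ||y - X b||, b >= 0.
nnls_solve <- function(X, y, tol = 1e-10) {
  p <- ncol(X)
  passive <- logical(p)
  b <- numeric(p)
  w <- crossprod(X, y - X %*% b)
  it <- 0L
  while (any(!passive & w > tol) && it < 30L * p) {
    it <- it + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      Xp <- X[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Xp), y)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) { b <- s; break }
      neg <- passive & s <= tol
      alpha <- min(b[neg] / (b[neg] - s[neg]))
      b <- b + alpha * (s - b)
      passive[passive & b <= tol] <- FALSE
      b[!passive] <- 0
    }
    w <- crossprod(X, y - X %*% b)
  }
  b
}

#' Project a frame onto the row space of S
#'
#' The low-rank display approximation: `A_hat = frame %*% P` with P the
#' orthogonal projector onto the span of the rows of S (built from the
#' non-degenerate rows via QR, so rank-deficient S is handled). Idempotent
#' and non-expansive.
#'
#' @param frame frame vector (length n).
#' @param S coefficient matrix with n columns.
#' @return list: `frame_hat`, `residual_norm`.
#' @export
reconstruct <- function(frame, S) {
  if (ncol(S) != length(frame)) stop("frame length does not match S")
  qrS <- qr(t(S))
  r <- qrS$rank
  if (r == 0) {
    hat <- numeric(length(frame))
  } else {
    Q <- qr.Q(qrS)[, seq_len(r), drop = FALSE]
    hat <- as.numeric(Q %*% crossprod(Q, frame))
  }
  list(frame_hat = hat, residual_norm = sqrt(sum((frame - hat)^2)))
}

# ---------------------------------------------------------------------------
# per-frame streaming loop

#' Initialise a streaming-analysis state
#'
#' The state is an environment mutated by [process_frame()]; per-frame
#' processing is a pure function of (state, frame) in the sense that the same
#' state content and frame always produce the same result and state update
#' (no hidden randomness).
#'
#' @param shape image shape `c(height, width)`.
#' @param k number of incremental principal components.
#' @param c number of convex-cone selections (response units).
#' @param filter_width spatial Gaussian width (odd; 1 = off) applied before
#'   normalisation.
#' @param sigma_floor dead-pixel guard for the z-score.
#' @param select_every run the convex-cone selection every this many frames
#'   (1 = every frame, as in the original per-frame loop; larger values thin
#'   the selection for throughput — the *final* model is unaffected because
#'   selection depends only on the current component matrix).
#' @param warmup frames that bypass factorisation (normalisation still
#'   updates); mirrors the guard on the first two time points.
#' @param nonneg clip the model's S at zero.
#' @param compute_recon compute the per-frame low-rank reconstruction.
#' @param amnesic CCIPCA forgetting parameter (see [update_ipca()]).
#' @param snapshot_maps also build a [build_map()] snapshot at each snapshot
#'   frame of [run_stream()].
#' @return environment of class `stream_state`.
#' @export
new_stream <- function(shape, k = 50, c = 50, filter_width = 9,
                       sigma_floor = 1e-6, select_every = 1L, warmup = 2L,
                       nonneg = TRUE, compute_recon = TRUE, amnesic = 0,
                       snapshot_maps = FALSE) {
  n <- prod(shape)
  st <- new.env(parent = emptyenv())
  st$shape <- as.integer(shape); st$n <- n
  st$k <- as.integer(k); st$c <- as.integer(c)
  st$filter_width <- filter_width; st$sigma_floor <- sigma_floor
  st$select_every <- as.integer(select_every); st$warmup <- as.integer(warmup)
  st$nonneg <- nonneg; st$compute_recon <- compute_recon
  st$amnesic <- amnesic; st$snapshot_maps <- snapshot_maps
  st$i <- 0L
  st$mean <- numeric(n); st$m2 <- numeric(n); st$count <- 0L
  st$V <- matrix(0, n, k); st$seeded <- 0L
  st$sel <- NULL; st$basis <- NULL; st$S <- NULL; st$S_chol <- NULL
  st$last_select <- 0L
  class(st) <- "stream_state"
  st
}

# Run the convex-cone selection on the current component matrix and cache the
# Cholesky factor of S S' used by the fast per-frame reconstruction.
select_units <- function(st) {
  active <- st$V[, seq_len(st$seeded), drop = FALSE]
  # early in the stream fewer than c columns clear the tolerance; the model
  # simply has fewer units until the subspace fills in
  cone <- convex_cone_cpp(t(active), st$c, 1e-9)
  st$sel <- cone$selected
  st$basis <- cone$basis
  st$S <- cone$S
  G <- tcrossprod(cone$S)
  ch <- tryCatch(chol(G + diag(1e-12 * max(diag(G), 1e-300), nrow(G))),
                 error = function(e) NULL)
  st$S_chol <- ch
  st$last_select <- st$i
  invisible(st)
}

#' Process one frame of the movie stream
#'
#' Applies the per-frame pipeline: spatial filter -> incremental z-score ->
#' CCIPCA update -> (periodically) convex-cone selection on the current
#' component matrix -> low-rank reconstruction of the normalised frame using
#' the current S. During warmup the frame passes through unmodified.
#'
#' @param st a [new_stream()] state (mutated).
#' @param frame raw frame vector (length `prod(shape)`).
#' @return list: `frame` (normalised), `frame_hat`, `residual_norm`,
#'   `selected`, `S`, `is_warmup`, `frame_index`.
#' @export
process_frame <- function(st, frame) {
  stopifnot(inherits(st, "stream_state"), length(frame) == st$n)
  st$i <- st$i + 1L
  f <- as.numeric(frame)
  if (st$filter_width > 1) f <- spatial_filter(f, st$shape, st$filter_width)
  z <- numeric(st$n)
  st$count <- welford_update_inplace(st$mean, st$m2, st$count, f, z,
                                     st$sigma_floor)
  if (st$i <= st$warmup)
    return(list(frame = z, frame_hat = as.numeric(frame),
                residual_norm = NA_real_, selected = NULL, S = NULL,
                is_warmup = TRUE, frame_index = st$i))
  st$seeded <- ccipca_update_inplace(st$V, st$seeded, z, st$i, 1e-12,
                                     st$amnesic)
  if (st$seeded > 0 &&
      (is.null(st$S) || (st$i - st$last_select) >= st$select_every))
    select_units(st)
  hat <- NULL; resid <- NA_real_
  if (st$compute_recon && !is.null(st$S)) {
    if (!is.null(st$S_chol)) {
      y <- st$S %*% z
      coef <- backsolve(st$S_chol, forwardsolve(t(st$S_chol), y))
      hat <- as.numeric(crossprod(st$S, coef))
      resid <- sqrt(sum((z - hat)^2))
    } else {
      rec <- reconstruct(z, st$S)
      hat <- rec$frame_hat; resid <- rec$residual_norm
    }
  }
  list(frame = z, frame_hat = hat, residual_norm = resid,
       selected = st$sel, S = st$S, is_warmup = FALSE, frame_index = st$i)
}

#' Run the streaming pipeline over a whole movie
#'
#' Iterates [process_frame()] over the rows of `A`, forces a final selection
#' on the last frame, and assembles the factor model: `selected` pixel
#' indices, the basis time series `T` (the final z-scored, filtered series of
#' the selected pixels, unit-normalised columns) and the coefficient images
#' `S` from the final convex-cone run on the component matrix.
#'
#' @param A movie matrix (frames x pixels) or a path readable by
#'   [read_movie()].
#' @param shape image shape; defaults to `attr(A, "shape")`.
#' @param snapshot_every record the selected pixel set every this many frames
#'   (`NULL`: only the final model). Selection is also (re)run at snapshot
#'   frames.
#' @param ... configuration passed to [new_stream()].
#' @return object of class `stream_run`: `model` (a `factor_model`), `pc`
#'   (final `pc_matrix`), `norm` (final `norm_state`), `snapshots`
#'   (data.frame frame/unit/pixel), `residuals` (per-frame relative residual
#'   where computed), `config`.
#' @export
run_stream <- function(A, shape = attr(A, "shape"), snapshot_every = NULL,
                       ...) {
  if (is.character(A)) { A <- read_movie(A); shape <- attr(A, "shape") }
  stopifnot(!is.null(shape))
  st <- new_stream(shape, ...)
  m <- nrow(A)
  resid <- rep(NA_real_, m)
  snaps <- list()
  snap_maps <- list()
  take_snap <- function(i) {
    if (!is.null(st$sel)) {
      snaps[[length(snaps) + 1L]] <<- data.frame(frame = i,
                                                 unit = seq_along(st$sel),
                                                 pixel = st$sel)
      if (st$snapshot_maps)
        snap_maps[[length(snap_maps) + 1L]] <<- build_map(st$S, shape,
                                                          frame_index = i)
    }
  }
  if (!st$compute_recon) {
    # chunked fast path: identical per-frame arithmetic, selection run at
    # the select_every / snapshot grid only (which is all the slow path
    # would expose without reconstructions)
    grid <- unique(sort(c(seq_len(m)[seq_len(m) %% st$select_every == 0L],
                          if (!is.null(snapshot_every))
                            seq_len(m)[seq_len(m) %% snapshot_every == 0L],
                          m)))
    Sr <- gaussian_smoother(shape[1], max(st$filter_width, 1))
    Sc <- gaussian_smoother(shape[2], max(st$filter_width, 1))
    prev <- 0L
    for (g in grid) {
      At <- t(A[(prev + 1L):g, , drop = FALSE])
      st$seeded <- stream_chunk_inplace(At, st$V, st$seeded, st$mean, st$m2,
                                        prev + 1L, st$warmup, Sr, Sc,
                                        st$filter_width > 1, st$sigma_floor,
                                        st$amnesic)
      st$i <- g
      st$count <- g
      if (st$seeded > 0L) select_units(st)
      at_snap <- !is.null(snapshot_every) &&
        (g %% snapshot_every == 0L || g == m)
      if (at_snap) take_snap(g)
      prev <- g
    }
  } else {
    for (i in seq_len(m)) {
      at_snap <- !is.null(snapshot_every) && (i %% snapshot_every == 0L || i == m)
      if (at_snap && st$i + 1L > st$warmup) {
        # force an up-to-date selection at snapshot frames
        old <- st$select_every; st$select_every <- 1L
        res <- process_frame(st, A[i, ])
        st$select_every <- old
      } else res <- process_frame(st, A[i, ])
      if (!is.null(res$residual_norm) && is.finite(res$residual_norm)) {
        nf <- sqrt(sum(res$frame^2))
        resid[i] <- if (nf > 0) res$residual_norm / nf else 0
      }
      if (at_snap) take_snap(i)
    }
  }
  if (st$seeded > 0 && (is.null(st$sel) || st$last_select < m))
    select_units(st)
  if (is.null(st$sel)) stop("stream too short: no components seeded")
  model <- assemble_model(A, st)
  structure(list(model = model,
                 pc = structure(list(components = st$V + 0, k = st$k, n = st$n,
                                     seeded = st$seeded, frames_seen = st$i,
                                     tol = 1e-12), class = "pc_matrix"),
                 norm = structure(list(count = st$count, mean = st$mean + 0,
                                       m2 = st$m2 + 0), class = "norm_state"),
                 snapshots = if (length(snaps)) do.call(rbind, snaps) else NULL,
                 snapshot_maps = if (length(snap_maps)) snap_maps else NULL,
                 residuals = resid,
                 config = list(k = st$k, c = st$c,
                               filter_width = st$filter_width,
                               select_every = st$select_every,
                               warmup = st$warmup, nonneg = st$nonneg)),
            class = "stream_run")
}

# Final factor model: T from the movie re-normalised with the final
# statistics (filtered series of the selected pixels only, so the full
# filtered movie is never materialised), S from the final cone run.
assemble_model <- function(A, st) {
  sel <- st$sel
  if (st$filter_width > 1) {
    # filtered series of pixel p = movie %*% (sparse smoothing weights of p)
    Sr <- gaussian_smoother(st$shape[1], st$filter_width)
    Sc <- gaussian_smoother(st$shape[2], st$filter_width)
    rc <- px_rowcol(sel, st$shape)
    Tsel <- matrix(0, nrow(A), length(sel))
    for (j in seq_along(sel)) {
      wimg <- outer(Sr[rc$row[j], ], Sc[rc$col[j], ])   # weights over the image
      nz <- which(wimg != 0)
      widx <- px_index(((nz - 1L) %% st$shape[1]) + 1L,
                       ((nz - 1L) %/% st$shape[1]) + 1L, st$shape)
      Tsel[, j] <- A[, widx, drop = FALSE] %*% wimg[nz]
    }
  } else {
    Tsel <- A[, sel, drop = FALSE]
  }
  sdv <- pmax(norm_state_sd(structure(list(count = st$count, mean = st$mean,
                                           m2 = st$m2), class = "norm_state")),
              st$sigma_floor)
  Tsel <- sweep(sweep(Tsel, 2, st$mean[sel], "-"), 2, sdv[sel], "/")
  cn <- sqrt(colSums(Tsel^2))
  cn[cn == 0] <- 1
  Tsel <- sweep(Tsel, 2, cn, "/")
  S <- st$S
  S_raw <- S
  if (st$nonneg) S <- pmax(S, 0)
  structure(list(selected = sel, T = Tsel, S = S, S_raw = S_raw,
                 basis = st$basis, c = length(sel), shape = st$shape),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d units, %dx%d px image, T is %d x %d\n",
              x$c, x$shape[1], x$shape[2], nrow(x$T), ncol(x$T)))
  invisible(x)
}

#' @export
print.stream_run <- function(x, ...) {
  cat(sprintf("stream_run: %d frames, k=%d, c=%d; median relative residual %.3g\n",
              x$pc$frames_seen, x$config$k, x$config$c,
              stats::median(x$residuals, na.rm = TRUE)))
  print(x$model)
  invisible(x)
}
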