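# Frame ingestion and per-frame preprocessing: Fura 340/380 ratio frames,
# spatial Gaussian smoothing, and incremental pixel-wise z-score
# normalisation. Frames are flattened row-major (pixel (r,c) -> r*width + c,
# 0-based), matching the on-disk contract.

#' Write a movie as a multi-page 32-bit TIFF stack
#'
#' TIFF samples are stored in `[0, 1]`; the movie is rescaled linearly and the
#' original range recorded in a JSON sidecar (`<path>.json`) so that
#' [read_movie()] restores the input values (float32 precision).
#'
#' @param A movie matrix (frames x pixels) with a `shape` attribute, or any
#'   matrix plus an explicit `shape`.
#' @param path output `.tif` path.
#' @param shape `c(height, width)`; defaults to `attr(A, "shape")`.
#' @export
write_movie_tiff <- function(A, path, shape = attr(A, "shape")) {
  stopifnot(!is.null(shape), ncol(A) == prod(shape))
  lo <- min(A); hi <- max(A)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(nrow(A)), function(i)
    frame_to_image((A[i, ] - lo) / scale, shape))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(min = lo, max = hi, shape = as.integer(shape),
                            n_frames = nrow(A)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calcium-imaging movie
#'
#' Reads either a multi-page TIFF stack or a directory of single-frame image
#' files (TIFF/PNG, sorted by file name, so zero-padded numeric names yield
#' temporal order). Frames are flattened row-major into the rows of the
#' returned matrix. If a `<path>.json` sidecar written by [write_movie_tiff()]
#' is present, the original intensity range is restored.
#'
#' @param path TIFF file or frame directory.
#' @param layout `"auto"`, `"tiff_stack"` or `"frame_directory"`.
#' @return `movie_matrix`: frames x pixels matrix with attribute `shape`.
#' @export
read_movie <- function(path, layout = c("auto", "tiff_stack", "frame_directory")) {
  layout <- match.arg(layout)
  if (layout == "auto")
    layout <- if (dir.exists(path)) "frame_directory" else "tiff_stack"
  if (layout == "tiff_stack") {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no frame images found in ", path)
    pages <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
      else tiff::readTIFF(f)
    })
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]                  # drop extra channels
    p
  })
  shape <- dim(pages[[1]])
  for (i in seq_along(pages))
    if (!identical(dim(pages[[i]]), shape))
      stop(sprintf("frame %d has shape %s, expected %s", i - 1L,
                   paste(dim(pages[[i]]), collapse = "x"),
                   paste(shape, collapse = "x")))
  A <- t(vapply(pages, image_to_frame, numeric(prod(shape))))
  if (nrow(A) != length(pages)) A <- matrix(A, nrow = length(pages))
  sidecar <- paste0(path, ".json")
  if (layout == "tiff_stack" && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    A <- A * (meta$max - meta$min) + meta$min
  }
  attr(A, "shape") <- as.integer(shape)
  class(A) <- c("movie_matrix", class(A))
  A
}

#' Fura-2 ratio frame
#'
#' Elementwise `f340 / (f380 + epsilon)`: the calcium-dependent,
#' bleaching-robust ratio of a consecutive 340 nm / 380 nm excitation pair.
#' The pair collapses to one time point at half the raw frame rate.
#'
#' @param f340,f380 frame vectors (same length).
#' @param epsilon small positive guard against zero denominators.
#' @export
ratio_frame <- function(f340, f380, epsilon = 1e-6) {
  if (length(f340) != length(f380)) stop("frame shape mismatch in ratio pair")
  f340 / (f380 + epsilon)
}

# Dense 1-D Gaussian smoothing operator (N x N) with reflecting boundary
# (mirror including the edge pixel). Column sums are exactly 1, so total
# intensity is preserved. Cached per (N, width).
.smoother_cache <- new.env(parent = emptyenv())
gaussian_smoother <- function(N, width) {
  key <- paste0(N, "_", width)
  hit <- .smoother_cache[[key]]
  if (!is.null(hit)) return(hit)
  half <- (width - 1L) %/% 2L
  g <- exp(-(-half:half)^2 / (2 * (width / 4)^2))
  g <- g / sum(g)
  S <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (t in -half:half) {
      j <- i + t
      while (j < 1L || j > N) {                  # reflect with edge repeat
        if (j < 1L) j <- 1L - j
        if (j > N) j <- 2L * N + 1L - j
      }
      S[i, j] <- S[i, j] + g[t + half + 1L]
    }
  }
  .smoother_cache[[key]] <- S
  S
}

#' Spatial Gaussian smoothing of a frame
#'
#' Separable 2-D Gaussian of kernel `width` pixels (sigma = width/4) with
#' reflecting boundary; `width = 1` is the identity. Total intensity is
#' preserved exactly. The default width 9 is the map-building preprocessing
#' used for the honeybee recordings.
#'
#' @param frame flattened frame vector (row-major).
#' @param shape `c(height, width)` of the image.
#' @param width odd kernel width in pixels.
#' @export
spatial_filter <- function(frame, shape, width = 9) {
  if (width %% 2 == 0 || width < 1) stop("filter width must be odd and >= 1")
  if (width == 1) return(frame)
  Sr <- gaussian_smoother(shape[1], width)
  Sc <- gaussian_smoother(shape[2], width)
  img <- frame_to_image(frame, shape)
  image_to_frame(Sr %*% tcrossprod(img, Sc))
}

#' New incremental normalisation state
#'
#' @param n number of pixels.
#' @return object of class `norm_state` holding frame count, running per-pixel
#'   mean and running sum of squared deviations (Welford one-pass scheme).
#' @export
norm_state_new <- function(n) {
  structure(list(count = 0L, mean = numeric(n), m2 = numeric(n)),
            class = "norm_state")
}

#' Incremental pixel-wise z-score normalisation
#'
#' Folds the frame into the running per-pixel mean and variance (numerically
#' stable one-pass update; population 1/N standard deviation) and returns the
#' frame z-scored with the *updated* statistics. The first frame therefore
#' normalises to all zeros, and early frames are inexact relative to
#' full-movie statistics; the estimates converge as the stream proceeds.
#' Zero-variance (dead) pixels are handled by `sigma_floor`.
#'
#' @param state a [norm_state_new()] object.
#' @param frame flattened frame vector.
#' @param sigma_floor lower bound on the per-pixel sd used for division.
#' @return list with elements `frame` (normalised) and `state` (updated).
#' @export
update_normalise <- function(state, frame, sigma_floor = 1e-6) {
  stopifnot(inherits(state, "norm_state"), length(frame) == length(state$mean))
  mean <- state$mean + 0; m2 <- state$m2 + 0          # unshared copies
  out <- numeric(length(frame))
  cnt <- welford_update_inplace(mean, m2, state$count, as.numeric(frame),
                                out, sigma_floor)
  list(frame = out,
       state = structure(list(count = cnt, mean = mean, m2 = m2),
                         class = "norm_state"))
}

#' Per-pixel standard deviation of a normalisation state
#' @param state a `norm_state`.
#' @export
norm_state_sd <- function(state) {
  if (state$count == 0L) return(numeric(length(state$mean)))
  sqrt(state$m2 / state$count)
}

#' Batch z-score of a full movie
#'
#' Column-wise (per-pixel) centring and scaling with population sd, floored at
#' `sigma_floor` — the statistics the streaming normaliser converges to.
#'
#' @param A movie matrix (frames x pixels).
#' @param sigma_floor lower bound on the per-pixel sd.
#' @export
zscore_movie <- function(A, sigma_floor = 1e-6) {
  mu <- colMeans(A)
  sdv <- sqrt(colMeans(A^2) - mu^2)
  sdv[!is.finite(sdv) | sdv < sigma_floor] <- sigma_floor
  Z <- sweep(A, 2, mu, "-")
  Z <- sweep(Z, 2, sdv, "/")
  attr(Z, "shape") <- attr(A, "shape")
  Z
}

#' Spatially filter every frame of a movie
#'
#' @inheritParams spatial_filter
#' @param A movie matrix (frames x pixels).
#' @export
filter_movie <- function(A, shape = attr(A, "shape"), width = 9) {
  if (width == 1) return(A)
  out <- A
  for (i in seq_len(nrow(A)))
    out[i, ] <- spatial_filter(A[i, ], shape, width)
  out
}

#' Collapse a dual-excitation stream to ratio frames
#'
#' Consecutive (340, 380) frame pairs are converted to single ratio frames at
#' half the raw frame rate: row 2i-1 over row 2i.
#'
#' @param A raw movie with alternating 340/380 frames in rows.
#' @param epsilon guard for zero denominators.
#' @export
ratio_movie <- function(A, epsilon = 1e-6) {
  m <- nrow(A) %/% 2L
  out <- matrix(0, m, ncol(A))
  for (i in seq_len(m))
    out[i, ] <- ratio_frame(A[2L * i - 1L, ], A[2L * i, ], epsilon)
  attr(out, "shape") <- attr(A, "shape")
  out
}
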