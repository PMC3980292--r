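# Functional maps: per-pixel unit assignment by overlaying the rows of S,
# incremental snapshots over the stream, and completeness tracking.

#' Build a unit map from coefficient images
#'
#' Pixel j is labelled with the row of S holding the largest (non-negative)
#' coefficient at j, provided that winning value clears the row's threshold;
#' otherwise the pixel is background (label 0). Ties go to the lower row
#' index. Threshold modes:
#' \describe{
#'   \item{`relative`}{(default) fraction `threshold` of the winning row's
#'     maximum — with 0.5 the labelled region is the coefficient image's
#'     full-width-half-maximum core.}
#'   \item{`quantile`}{quantile `threshold` of the winning row's values.}
#'   \item{`absolute`}{fixed cutoff.}
#' }
#' Both `relative` and `quantile` labelling are invariant to positive
#' rescaling of any single row of S.
#'
#' @param S c x n coefficient matrix (rows = units); negative entries are
#'   treated as zero.
#' @param shape image shape `c(height, width)`.
#' @param threshold_mode `"relative"`, `"quantile"` or `"absolute"`.
#' @param threshold numeric threshold parameter for the chosen mode.
#' @param frame_index optional stream time of the snapshot.
#' @return object of class `unit_map`: `labels` (n-vector, 0 = background),
#'   `confidence` (winning coefficient), `shape`, `frame_index`.
#' @export
build_map <- function(S, shape, threshold_mode = c("relative", "quantile",
                                                   "absolute"),
                      threshold = 0.5, frame_index = NA_integer_) {
  threshold_mode <- match.arg(threshold_mode)
  if (nrow(S) < 1) stop("S must have at least one row")
  Sp <- pmax(S, 0)
  if (threshold_mode != "absolute") {
    # the cone leaves per-row scale ambiguous: compete on peak-normalised
    # rows so labelling is invariant to rescaling any single row
    rmax <- apply(Sp, 1, max)
    Sp <- sweep(Sp, 1, ifelse(rmax > 0, rmax, 1), "/")
  }
  win <- max.col(t(Sp), ties.method = "first")   # argmax over rows, low index ties
  conf <- Sp[cbind(win, seq_len(ncol(Sp)))]
  cut <- switch(threshold_mode,
                relative = rep(threshold, nrow(Sp)),
                quantile = apply(Sp, 1, quantile, probs = threshold, names = FALSE),
                absolute = rep(threshold, nrow(Sp)))
  labels <- ifelse(conf > cut[win] & conf > 0, win, 0L)
  structure(list(labels = as.integer(labels), confidence = conf,
                 shape = as.integer(shape), n_units = nrow(S),
                 frame_index = frame_index),
            class = "unit_map")
}

#' @export
print.unit_map <- function(x, ...) {
  cat(sprintf("unit_map: %d units, %d labelled of %d pixels (%dx%d)\n",
              x$n_units, sum(x$labels > 0), length(x$labels),
              x$shape[1], x$shape[2]))
  invisible(x)
}

#' Unit-recovery completeness over the stream
#'
#' For each selection snapshot of a [run_stream()] result, the fraction of
#' ground-truth units hit by at least one selected pixel. As the movie stream
#' grows, the incremental estimates improve and the map fills in.
#'
#' @param run a `stream_run` produced with `snapshot_every` set.
#' @param truth the `ground_truth` of the movie.
#' @return data.frame with columns `frame` and `completeness`.
#' @export
map_completeness <- function(run, truth) {
  if (is.null(run$snapshots)) stop("run has no snapshots; set snapshot_every")
  frames <- unique(run$snapshots$frame)
  comp <- vapply(frames, function(f) {
    sel <- run$snapshots$pixel[run$snapshots$frame == f]
    mean(units_hit(sel, truth))
  }, numeric(1))
  data.frame(frame = frames, completeness = comp)
}

#' Per-unit overlap of map regions with true footprint cores
#'
#' For every true unit, the union of the map regions of all model units whose
#' selected pixel lies inside that unit's footprint is compared with the
#' unit's core — the footprint disc (all pixels with non-zero mixing weight)
#' — by Jaccard index. Units hit by no selection score 0.
#'
#' @param map a [build_map()] result.
#' @param model the `factor_model` the map was built from.
#' @param truth the `ground_truth`.
#' @return numeric vector of Jaccard indices, one per true unit.
#' @export
map_truth_jaccard <- function(map, model, truth) {
  vapply(seq_len(truth$n_units), function(u) {
    core <- which(truth$mixing[u, ] > 0)
    mine <- which(truth$mixing[u, model$selected] > 0)
    if (length(mine) == 0) return(0)
    region <- which(map$labels %in% mine)
    length(intersect(region, core)) / length(union(region, core))
  }, numeric(1))
}

#' Render a unit map as an RGB image
#'
#' Deterministic distinct colours per unit (golden-angle hue rotation,
#' permuted by `palette_seed`); background black.
#'
#' @param map a `unit_map`.
#' @param palette_seed seed for the colour permutation.
#' @return list: `rgb` (height x width x 3 array in `[0,1]`), `legend`
#'   (data.frame unit/colour hex).
#' @export
render_map <- function(map, palette_seed = 1) {
  cmax <- max(map$n_units, 1L)
  hues <- (0.12 + (seq_len(cmax) - 1) * 0.381966011250105) %% 1
  cols <- grDevices::hsv(hues, s = 0.75, v = 0.95)
  cols <- with_seed(palette_seed, sample(cols))
  rgbm <- grDevices::col2rgb(cols) / 255
  img <- array(0, dim = c(map$shape[1], map$shape[2], 3))
  lab <- frame_to_image(map$labels, map$shape)
  for (ch in 1:3) {
    plane <- matrix(0, map$shape[1], map$shape[2])
    nz <- lab > 0
    plane[nz] <- rgbm[ch, lab[nz]]
    img[, , ch] <- plane
  }
  list(rgb = img,
       legend = data.frame(unit = seq_len(cmax), colour = cols))
}

#' Write a unit map to disk
#'
#' Writes a 16-bit label TIFF, an RGB PNG and a CSV
#' (`pixel_row,pixel_col,unit,confidence`, 0-based coordinates) sharing the
#' stem `path`.
#'
#' @param map a `unit_map`.
#' @param path output stem (without extension).
#' @param palette_seed passed to [render_map()].
#' @export
write_map <- function(map, path, palette_seed = 1) {
  lab16 <- frame_to_image(map$labels / 65535, map$shape)
  tiff::writeTIFF(lab16, paste0(path, "_labels.tif"), bits.per.sample = 16L)
  rm_ <- render_map(map, palette_seed)
  png::writePNG(rm_$rgb, paste0(path, ".png"))
  write.csv(rm_$legend, paste0(path, "_legend.csv"), row.names = FALSE)
  keep <- which(map$labels > 0)
  rc <- px_rowcol(keep, map$shape)
  write.csv(data.frame(pixel_row = rc$row - 1L, pixel_col = rc$col - 1L,
                       unit = map$labels[keep],
                       confidence = map$confidence[keep]),
            paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' Map snapshots over the stream
#'
#' Returns the sequence of incrementally updated unit maps recorded during a
#' [run_stream()] call made with `snapshot_every` and `snapshot_maps = TRUE`,
#' together with the completeness timeline when ground truth is supplied —
#' the way a functional map develops during a real-time experiment.
#'
#' @param run a `stream_run`.
#' @param truth optional `ground_truth` for the completeness column.
#' @return list: `maps` (list of `unit_map` snapshots), `completeness`
#'   (data.frame, or NULL without truth).
#' @export
map_timeline <- function(run, truth = NULL) {
  if (is.null(run$snapshot_maps))
    stop("run has no map snapshots; use snapshot_every and snapshot_maps = TRUE")
  list(maps = run$snapshot_maps,
       completeness = if (!is.null(truth)) map_completeness(run, truth))
}
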