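# Synthetic calcium-imaging movies with known ground truth.
#
# Movies follow the non-negative mixture model the factorisation assumes:
# the movie matrix A (frames x pixels) is traces %*% mixing plus an optional
# multiplicative-bleaching baseline trend and i.i.d. Gaussian sensor noise.
# Each response unit ("glomerulus") has a truncated-Gaussian spatial footprint
# whose fringes may overlap neighbouring units (light scatter) while its
# centre pixel stays pure, so the identifiability condition of the convex-cone
# selection holds by construction.

#' Generate a stimulus protocol
#'
#' Builds an ordered stimulus sequence with onset frames. Non-reference labels
#' are presented once each in seeded random order; reference (control) labels
#' are interleaved so that every `reference_every`-th presentation is a
#' reference, cycling through the reference labels round-robin until each has
#' been presented `n_reference_repeats` times (left-over reference
#' presentations are appended at the end).
#'
#' @param labels character vector of stimulus labels (each presented once
#'   unless listed in `reference_labels`).
#' @param reference_labels labels presented repeatedly as references/controls.
#' @param n_reference_repeats presentations per reference label.
#' @param reference_every place a reference at every this-many-th position.
#' @param interstimulus_frames frames between consecutive onsets (>= 1).
#' @param frame_rate acquisition rate in Hz.
#' @param lead_in_frames frames before the first onset.
#' @param seed integer seed for the label shuffle.
#' @return object of class `stimulus_protocol`: data.frame with columns
#'   `label` and `onset_frame` (0-based frame of stimulus onset), with
#'   attributes `n_frames` and `frame_rate`.
#' @export
generate_protocol <- function(labels, reference_labels = NULL,
                              n_reference_repeats = 0, reference_every = 5,
                              interstimulus_frames = 30, frame_rate = 5,
                              lead_in_frames = 0, seed = 1) {
  if (length(labels) == 0) stop("labels must be non-empty")
  if (interstimulus_frames < 1) stop("interstimulus_frames must be >= 1")
  others <- setdiff(labels, reference_labels)
  others <- with_seed(seed, sample(others))
  refs <- character(0)
  if (length(reference_labels) > 0 && n_reference_repeats > 0)
    refs <- rep(reference_labels, times = n_reference_repeats)  # round-robin
  seq_labels <- character(0)
  oi <- 1L; ri <- 1L
  while (oi <= length(others) || ri <= length(refs)) {
    if ((length(seq_labels) + 1L) %% reference_every == 0 && ri <= length(refs)) {
      seq_labels <- c(seq_labels, refs[ri]); ri <- ri + 1L
    } else if (oi <= length(others)) {
      seq_labels <- c(seq_labels, others[oi]); oi <- oi + 1L
    } else {
      seq_labels <- c(seq_labels, refs[ri]); ri <- ri + 1L
    }
  }
  n <- length(seq_labels)
  onsets <- lead_in_frames + (seq_len(n) - 1L) * interstimulus_frames
  proto <- data.frame(label = seq_labels, onset_frame = as.integer(onsets),
                      stringsAsFactors = FALSE)
  attr(proto, "n_frames") <- as.integer(lead_in_frames + n * interstimulus_frames)
  attr(proto, "frame_rate") <- frame_rate
  class(proto) <- c("stimulus_protocol", "data.frame")
  proto
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("stimulus_protocol: %d presentations, %d frames at %g Hz\n",
              nrow(x), attr(x, "n_frames"), attr(x, "frame_rate")))
  print.data.frame(head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Noise level for a target signal-to-noise ratio
#'
#' SNR is defined as mean stimulus-response amplitude over sensor noise
#' standard deviation.
#'
#' @param snr target ratio.
#' @param amplitude mean response amplitude (the generator default is 1).
#' @export
snr_noise_sigma <- function(snr, amplitude = 1) amplitude / snr

# Calcium-transient kernel: difference of exponentials, 0.5 s rise and 3 s
# decay, peak-normalised to 1.
stimulus_kernel <- function(frame_rate, rise_s = 0.5, decay_s = 3) {
  tau_r <- rise_s * frame_rate
  tau_d <- decay_s * frame_rate
  t <- 0:ceiling(5 * tau_d)
  k <- exp(-t / tau_d) - exp(-t / tau_r)
  k / max(k)
}

#' Draw a units x labels response-amplitude matrix
#'
#' Each unit responds to each label with probability `response_prob`
#' (amplitude uniform in `amplitude_range`, at least one responsive label per
#' unit). Passing the same matrix to [generate_ground_truth()] for several
#' synthetic "individuals" gives them a common odour-response structure while
#' footprints, spontaneous activity and noise stay independent.
#'
#' Reference odours model the strong, reliable ligands an experimenter picks
#' as controls: their columns are drawn with a higher response probability
#' and amplitudes from the upper part of the range.
#'
#' @param n_units number of response units.
#' @param labels stimulus labels (unique).
#' @param seed integer seed.
#' @param response_prob probability a unit responds to a label.
#' @param amplitude_range amplitude bounds.
#' @param reference_labels labels treated as strong reference ligands.
#' @param reference_prob response probability for reference labels.
#' @param reference_amplitude_range amplitude bounds for reference labels.
#' @export
draw_response_amplitudes <- function(n_units, labels, seed,
                                     response_prob = 0.25,
                                     amplitude_range = c(0.5, 1.5),
                                     reference_labels = NULL,
                                     reference_prob = 0.4,
                                     reference_amplitude_range = c(0.8, 1.5)) {
  with_seed(seed, {
    amp <- matrix(0, n_units, length(labels), dimnames = list(NULL, labels))
    for (u in seq_len(n_units)) {
      resp <- runif(length(labels)) < response_prob
      if (!any(resp)) resp[sample.int(length(labels), 1)] <- TRUE
      amp[u, resp] <- runif(sum(resp), amplitude_range[1], amplitude_range[2])
    }
    for (lab in intersect(reference_labels, labels)) {
      resp <- runif(n_units) < reference_prob
      if (sum(resp) < 2) resp[sample.int(n_units, 2)] <- TRUE
      amp[, lab] <- 0
      amp[resp, lab] <- runif(sum(resp), reference_amplitude_range[1],
                              reference_amplitude_range[2])
    }
    amp
  })
}

# Temporally smoothed unit-variance Gaussian noise, rescaled to sd `amp`.
smoothed_noise <- function(m, sigma_frames, amp) {
  if (amp <= 0) return(numeric(m))
  half <- max(1L, ceiling(3 * sigma_frames))
  g <- exp(-((-half):half)^2 / (2 * sigma_frames^2))
  g <- g / sum(g)
  x <- rnorm(m + 2 * half)
  y <- as.numeric(stats::filter(x, g, sides = 2))
  y <- y[(half + 1):(half + m)]
  s <- sd(y)
  if (!is.finite(s) || s == 0) return(numeric(m))
  amp * y / s
}

# Truncated-Gaussian footprint: sigma = radius / 2, cut at 2*sigma (= radius),
# peak 1 at the centre. Returns the flattened (row-major) weight vector.
footprint_profile <- function(center, radius, shape) {
  sigma <- radius / 2
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(shape[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(shape[2], ceiling(center[2] + radius))
  w <- numeric(prod(shape))
  for (r in r0:r1) {
    cc <- c0:c1
    d2 <- (r - center[1])^2 + (cc - center[2])^2
    keep <- d2 <= radius^2
    if (any(keep))
      w[px_index(r, cc[keep], shape)] <- exp(-d2[keep] / (2 * sigma^2))
  }
  w
}

#' Generate ground truth for a synthetic movie
#'
#' Places `n_units` circular response units with truncated-Gaussian footprints
#' (sigma = radius/2, support cut at the radius) such that unit centres never
#' fall inside another unit's support: centres are required to be at least
#' 0.8 x (sum of the two radii) apart, which keeps every centre pixel pure
#' (exactly one non-zero mixing entry) while footprint fringes may overlap
#' (simulated light scatter). Each unit responds to a seeded random subset of
#' stimulus labels (probability `response_prob`, amplitude drawn from
#' `amplitude_range`, at least one responsive label per unit) with a
#' difference-of-exponentials calcium transient (0.5 s rise, 3 s decay), plus
#' low-amplitude smoothed-Gaussian spontaneous activity. Optional large smooth
#' "artifact" structures with slow temporal drift emulate background staining
#' and illumination inhomogeneities seen in real recordings.
#'
#' @param shape integer `c(height, width)` in pixels.
#' @param n_units number of response units (>= 1).
#' @param protocol a [generate_protocol()] object.
#' @param radius_range footprint radius bounds in pixels.
#' @param noise_sigma sensor noise standard deviation (see [snr_noise_sigma()]).
#' @param bleach_tau photobleaching time constant in frames (`NULL`: no
#'   bleaching / baseline term, e.g. ratio-corrected data).
#' @param seed integer seed; the full ground truth is deterministic in it.
#' @param amplitude_range response amplitude bounds.
#' @param response_prob probability a unit responds to a given label.
#' @param response_amplitudes optional pre-specified units x labels amplitude
#'   matrix (colnames = unique labels); overrides the random draw, so two
#'   synthetic "individuals" can share one odour-response structure.
#' @param spontaneous_amplitude sd of the smoothed spontaneous component.
#' @param n_artifacts number of background/illumination artifact structures.
#' @param artifact_amplitude sd of the slow artifact fluctuation.
#' @param ensure_pure verify every unit keeps a pure centre pixel.
#' @return object of class `ground_truth`.
#' @export
generate_ground_truth <- function(shape, n_units, protocol,
                                  radius_range = c(5, 9),
                                  noise_sigma = 0.2, bleach_tau = NULL,
                                  seed = 1,
                                  amplitude_range = c(0.5, 1.5),
                                  response_prob = 0.25,
                                  response_amplitudes = NULL,
                                  spontaneous_amplitude = 0.1,
                                  n_artifacts = 6,
                                  artifact_amplitude = 0.15,
                                  ensure_pure = TRUE) {
  stopifnot(n_units >= 1, length(shape) == 2)
  m <- attr(protocol, "n_frames")
  frame_rate <- attr(protocol, "frame_rate")
  n <- prod(shape)
  ulabels <- unique(protocol$label)

  truth <- with_seed(seed, {
    # --- placement -------------------------------------------------------
    radii <- runif(n_units, radius_range[1], radius_range[2])
    centers <- matrix(NA_real_, n_units, 2)
    for (u in seq_len(n_units)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        cand <- c(runif(1, radii[u] + 1, shape[1] - radii[u]),
                  runif(1, radii[u] + 1, shape[2] - radii[u]))
        if (u == 1L) { ok <- TRUE } else {
          prev <- seq_len(u - 1L)
          dsep <- sqrt((centers[prev, 1] - cand[1])^2 + (centers[prev, 2] - cand[2])^2)
          ok <- all(dsep >= 0.8 * (radii[prev] + radii[u]))
        }
        if (ok) { centers[u, ] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stop(sprintf("image %dx%d too small to place unit %d of %d",
                     shape[1], shape[2], u, n_units))
    }
    footprints <- lapply(seq_len(n_units), function(u)
      list(center = centers[u, ], radius = radii[u],
           profile = footprint_profile(centers[u, ], radii[u], shape)))
    mixing <- do.call(rbind, lapply(footprints, `[[`, "profile"))

    # --- response amplitudes --------------------------------------------
    if (is.null(response_amplitudes)) {
      amp <- matrix(0, n_units, length(ulabels), dimnames = list(NULL, ulabels))
      for (u in seq_len(n_units)) {
        resp <- runif(length(ulabels)) < response_prob
        if (!any(resp)) resp[sample.int(length(ulabels), 1)] <- TRUE
        amp[u, resp] <- runif(sum(resp), amplitude_range[1], amplitude_range[2])
      }
    } else {
      amp <- response_amplitudes[, ulabels, drop = FALSE]
      stopifnot(nrow(amp) == n_units)
    }

    # --- source traces ---------------------------------------------------
    kern <- stimulus_kernel(frame_rate)
    traces <- matrix(0, m, n_units)
    for (u in seq_len(n_units)) {
      tr <- smoothed_noise(m, frame_rate, spontaneous_amplitude)
      for (s in seq_len(nrow(protocol))) {
        a <- amp[u, protocol$label[s]]
        if (a > 0) {
          o <- protocol$onset_frame[s] + 1L         # protocol onsets are 0-based
          idx <- o:min(m, o + length(kern) - 1L)
          tr[idx] <- tr[idx] + a * kern[seq_along(idx)]
        }
      }
      traces[, u] <- tr
    }

    # --- artifacts -------------------------------------------------------
    art_mixing <- NULL; art_traces <- NULL
    if (n_artifacts > 0) {
      art_mixing <- matrix(0, n_artifacts, n)
      art_traces <- matrix(0, m, n_artifacts)
      for (a in seq_len(n_artifacts)) {
        ar <- runif(1, 0.12, 0.25) * min(shape)
        ac <- c(runif(1, 1, shape[1]), runif(1, 1, shape[2]))
        art_mixing[a, ] <- runif(1, 0.5, 1) * footprint_profile(ac, ar, shape)
        art_traces[, a] <- smoothed_noise(m, 10 * frame_rate, artifact_amplitude)
      }
    }

    baseline <- 1 + 0.5 * colSums(mixing)
    list(radii = radii, centers = centers, footprints = footprints,
         mixing = mixing, amp = amp, traces = traces,
         art_mixing = art_mixing, art_traces = art_traces, baseline = baseline)
  })

  pure <- px_index(round(truth$centers[, 1]), round(truth$centers[, 2]), shape)
  if (ensure_pure) {
    for (u in seq_len(n_units)) {
      col <- truth$mixing[, pure[u]]
      if (sum(col > 0) != 1L || which.max(col) != u)
        stop(sprintf("unit %d lost its pure centre pixel", u))
    }
  }

  sources <- lapply(seq_len(n_units), function(u)
    list(unit_id = u, trace = truth$traces[, u],
         stimulus_responses = truth$amp[u, ],
         spontaneous_amplitude = spontaneous_amplitude))

  out <- list(shape = as.integer(shape), n_units = n_units, m = m,
              frame_rate = frame_rate, protocol = protocol,
              footprints = truth$footprints, sources = sources,
              mixing = truth$mixing, traces = truth$traces,
              response_amplitudes = truth$amp,
              artifact_mixing = truth$art_mixing,
              artifact_traces = truth$art_traces,
              baseline = truth$baseline,
              noise_sigma = noise_sigma, bleach_tau = bleach_tau,
              pure_pixels = pure, seed = seed,
              noise_seed = (seed %% 1000000000L) + 7919L)
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d units on %dx%d px, %d frames at %g Hz\n",
              x$n_units, x$shape[1], x$shape[2], x$m, x$frame_rate))
  cat(sprintf("  noise sd %.3g, bleaching %s, %d artifact structures\n",
              x$noise_sigma,
              if (is.null(x$bleach_tau)) "off" else sprintf("tau=%g", x$bleach_tau),
              if (is.null(x$artifact_mixing)) 0L else nrow(x$artifact_mixing)))
  invisible(x)
}

#' Render a movie matrix from ground truth
#'
#' `A = traces %*% mixing` plus artifact structures, plus
#' `exp(-t/bleach_tau)` times the baseline image when bleaching is enabled,
#' plus i.i.d. Gaussian noise of sd `noise_sigma`. With noise off, bleaching
#' off and no artifacts the output is the exact non-negative mixture.
#'
#' @param truth a [generate_ground_truth()] object.
#' @return `m x n` movie matrix (class `movie_matrix`), frames in rows,
#'   pixels flattened row-major; attribute `shape`.
#' @export
render_movie <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  A <- truth$traces %*% truth$mixing
  if (!is.null(truth$artifact_mixing))
    A <- A + truth$artifact_traces %*% truth$artifact_mixing
  if (!is.null(truth$bleach_tau)) {
    fade <- exp(-(seq_len(truth$m) - 1) / truth$bleach_tau)
    A <- A + outer(fade, truth$baseline)
  }
  if (truth$noise_sigma > 0)
    A <- A + with_seed(truth$noise_seed,
                       matrix(rnorm(length(A), sd = truth$noise_sigma),
                              nrow(A), ncol(A)))
  attr(A, "shape") <- truth$shape
  class(A) <- c("movie_matrix", class(A))
  A
}

#' Ground truth plus rendered movie in one call
#'
#' @inheritParams generate_ground_truth
#' @param ... passed to [generate_ground_truth()].
#' @return list with elements `truth` and `movie`.
#' @export
generate_movie <- function(shape, n_units, protocol, ...) {
  truth <- generate_ground_truth(shape, n_units, protocol, ...)
  list(truth = truth, movie = render_movie(truth))
}

# ---------------------------------------------------------------------------
# plain-text export

#' Write a stimulus protocol as CSV (`label,onset_frame`)
#' @param protocol a `stimulus_protocol`.
#' @param path output file.
#' @export
write_protocol <- function(protocol, path) {
  write.csv(as.data.frame(protocol)[, c("label", "onset_frame")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stimulus protocol CSV
#' @param path CSV with columns `label,onset_frame` (onsets 0-based).
#' @param n_frames,frame_rate movie length and rate; `n_frames` defaults to
#'   last onset plus the median inter-onset gap.
#' @export
read_protocol <- function(path, n_frames = NULL, frame_rate = 5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "onset_frame") %in% names(df)))
  if (is.null(n_frames)) {
    gap <- if (nrow(df) > 1) stats::median(diff(df$onset_frame)) else 1
    n_frames <- max(df$onset_frame) + gap
  }
  attr(df, "n_frames") <- as.integer(n_frames)
  attr(df, "frame_rate") <- frame_rate
  class(df) <- c("stimulus_protocol", "data.frame")
  df
}

#' Export ground truth as a plain-text dataset directory
#'
#' Writes `mixing.csv` (units x pixels), `traces.csv` (frames x units),
#' `pure_pixels.csv`, `protocol.csv` and `manifest.json` into `dir`.
#'
#' @param truth a `ground_truth`.
#' @param dir output directory (created if missing).
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(truth$mixing, file.path(dir, "mixing.csv"), row.names = FALSE)
  write.csv(truth$traces, file.path(dir, "traces.csv"), row.names = FALSE)
  rc <- px_rowcol(truth$pure_pixels, truth$shape)
  write.csv(data.frame(unit = seq_len(truth$n_units),
                       pixel = truth$pure_pixels - 1L,     # 0-based on disk
                       row = rc$row - 1L, col = rc$col - 1L),
            file.path(dir, "pure_pixels.csv"), row.names = FALSE)
  write_protocol(truth$protocol, file.path(dir, "protocol.csv"))
  jsonlite::write_json(list(shape = truth$shape, n_units = truth$n_units,
                            m = truth$m, frame_rate = truth$frame_rate,
                            noise_sigma = truth$noise_sigma,
                            bleach_tau = truth$bleach_tau,
                            seed = truth$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
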