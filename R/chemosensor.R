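# Downstream chemosensing analysis: per-stimulus odour feature vectors from
# the response-unit time series, hierarchical clustering (Ward), odour x
# odour Euclidean distance matrices, and the Mantel permutation test for
# cross-individual correspondence of odour representations.

#' Per-stimulus response features
#'
#' For each protocol entry, the feature of a response unit is the maximum of
#' its time series in the window from the stimulus onset to the next onset
#' (the last window runs to the end of the movie). Optionally the pre-onset
#' baseline (mean of the 5 frames before onset) is subtracted — useful when
#' slow drifts such as bleaching would otherwise bias the maxima.
#'
#' @param T frames x units matrix of response-unit time series.
#' @param protocol a `stimulus_protocol` covering all onsets (0-based).
#' @param baseline_mode `"none"` (raw window maxima) or `"pre_onset"`.
#' @return object of class `feature_matrix`: `values` (stimuli x units),
#'   `stimulus_labels`, `unit_ids`.
#' @export
extract_features <- function(T, protocol, baseline_mode = c("none", "pre_onset")) {
  baseline_mode <- match.arg(baseline_mode)
  m <- nrow(T)
  onsets <- protocol$onset_frame + 1L            # to 1-based frames
  if (any(onsets > m)) stop("time series does not cover all protocol onsets")
  ends <- c(onsets[-1] - 1L, m)
  vals <- matrix(NA_real_, nrow(protocol), ncol(T))
  for (s in seq_len(nrow(protocol))) {
    if (ends[s] < onsets[s]) stop("empty stimulus window at entry ", s)
    win <- T[onsets[s]:ends[s], , drop = FALSE]
    f <- apply(win, 2, max)
    if (baseline_mode == "pre_onset") {
      b0 <- max(1L, onsets[s] - 5L)
      if (onsets[s] > 1L)
        f <- f - colMeans(T[b0:(onsets[s] - 1L), , drop = FALSE])
    }
    vals[s, ] <- f
  }
  uid <- colnames(T)
  if (is.null(uid)) uid <- as.character(seq_len(ncol(T)))
  structure(list(values = vals, stimulus_labels = protocol$label,
                 unit_ids = uid),
            class = "feature_matrix")
}

#' Pairwise Euclidean distances between stimulus feature vectors
#'
#' @param F a [extract_features()] result (or a plain stimuli x units matrix).
#' @return object of class `distance_matrix`: symmetric matrix `d` with zero
#'   diagonal and `labels`.
#' @export
euclidean_distances <- function(F) {
  vals <- if (inherits(F, "feature_matrix")) F$values else as.matrix(F)
  labels <- if (inherits(F, "feature_matrix")) F$stimulus_labels
            else rownames(vals)
  if (nrow(vals) < 2) stop("need at least two stimuli")
  d <- as.matrix(dist(vals, method = "euclidean"))
  dimnames(d) <- NULL
  structure(list(d = d, labels = labels), class = "distance_matrix")
}

#' Ward hierarchical clustering of odour feature vectors
#'
#' Agglomerative clustering under Ward's minimum-variance criterion on
#' Euclidean geometry (`stats::hclust`, method `ward.D2`, which applies
#' Ward's criterion to unsquared Euclidean distances). Deterministic given
#' the input order; merge heights are non-decreasing.
#'
#' @param x a `feature_matrix`, `distance_matrix`, `dist` or numeric matrix
#'   of feature vectors (rows = items).
#' @return an `hclust` tree with leaf labels.
#' @export
ward_cluster <- function(x) {
  if (inherits(x, "feature_matrix")) {
    d <- dist(x$values)
    attr(d, "Labels") <- x$stimulus_labels
  } else if (inherits(x, "distance_matrix")) {
    d <- stats::as.dist(x$d)
    attr(d, "Labels") <- x$labels
  } else if (inherits(x, "dist")) {
    d <- x
  } else {
    x <- as.matrix(x)
    if (nrow(x) < 2) stop("need at least two items")
    d <- dist(x)
  }
  hclust(d, method = "ward.D2")
}

#' Does a label's set of leaves form a pure subtree?
#'
#' TRUE when some internal node of the tree has exactly the leaves carrying
#' `label` below it (i.e. the replicates of a reference odour merge with each
#' other before anything else joins them).
#'
#' @param hc an `hclust` tree with leaf labels.
#' @param label the leaf label whose replicates are checked.
#' @export
is_pure_subtree <- function(hc, label) {
  target <- which(hc$labels == label)
  if (length(target) <= 1) return(TRUE)
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  leaves_of <- function(i) if (i < 0) -i else members[[i]]
  for (j in seq_len(nrow(hc$merge))) {
    members[[j]] <- c(leaves_of(hc$merge[j, 1]), leaves_of(hc$merge[j, 2]))
    if (setequal(members[[j]], target)) return(TRUE)
  }
  FALSE
}

#' Mantel permutation test for two distance matrices
#'
#' Pearson correlation of the upper-triangle entries; the null distribution
#' is generated by jointly permuting the rows and columns of the second
#' matrix. Two-tailed on |r|; the +1 correction makes p = 0 impossible.
#'
#' @param D1,D2 `distance_matrix` objects or plain symmetric matrices with
#'   matching item order.
#' @param n_permutations number of permutations (>= 1).
#' @param seed RNG seed; the test is deterministic per seed.
#' @return list: `r` (Pearson correlation), `p` (permutation p-value),
#'   `n_permutations`.
#' @export
mantel_test <- function(D1, D2, n_permutations = 999, seed = 0) {
  d1 <- if (inherits(D1, "distance_matrix")) D1$d else as.matrix(D1)
  d2 <- if (inherits(D2, "distance_matrix")) D2$d else as.matrix(D2)
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in size")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  n <- nrow(d1)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  r <- cor(v1, d2[ut])
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_permutations)) {
      p <- sample.int(n)
      rp <- cor(v1, d2[p, p][ut])
      if (abs(rp) >= abs(r)) cnt <- cnt + 1L
    }
    cnt
  })
  list(r = r, p = (exceed + 1) / (n_permutations + 1),
       n_permutations = n_permutations)
}

#' Export an hclust tree as a Newick string
#'
#' Nested-parenthesis tree with branch lengths derived from the merge
#' heights (requires the `ape` package).
#'
#' @param hc an `hclust` tree.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when writing to file.
#' @export
export_newick <- function(hc, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for Newick export")
  phy <- ape::as.phylo(hc)
  s <- ape::write.tree(phy)
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}

#' Write a feature matrix as CSV (rows = stimuli)
#' @param F a `feature_matrix`.
#' @param path output file.
#' @export
write_features <- function(F, path) {
  df <- as.data.frame(F$values)
  names(df) <- F$unit_ids
  df <- cbind(stimulus = F$stimulus_labels, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Clustered heatmap of odour feature vectors
#'
#' Stimuli x units heatmap with Ward clustering on both axes, optionally on
#' a log colour scale (features stay linear on disk; the log is a rendering
#' choice only). Requires the `pheatmap` package.
#'
#' @param F a `feature_matrix`.
#' @param path output PNG file.
#' @param log_scale colour on log10(1 + x) of the shifted features.
#' @export
feature_heatmap <- function(F, path, log_scale = TRUE) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("the pheatmap package is required for heatmaps")
  vals <- F$values
  rownames(vals) <- make.unique(F$stimulus_labels)
  colnames(vals) <- F$unit_ids
  if (log_scale) vals <- log10(1 + pmax(vals - min(vals), 0))
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(vals, clustering_method = "ward.D2")
  invisible(path)
}
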