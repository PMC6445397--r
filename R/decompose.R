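#' Principal component analysis of a methylation matrix
#'
#' Samples are observations, features (DMRs) are variables. Features are
#' centered but not scaled; the decomposition is an exact SVD
#' ([stats::prcomp()]). Each component's sign is fixed deterministically:
#' the loading of largest magnitude is made positive.
#'
#' @param values Features x samples numeric matrix, no missing values.
#' @param n_components Number of components to return (default: all
#'   available, i.e. `min(n_samples, n_features)`).
#' @param sample_metadata Optional per-sample data frame carried along.
#' @return Object of class `meth_pca`: `scores` (samples x components),
#'   `loadings` (features x components), `explained_variance_ratio`,
#'   `feature_ids`, `sample_metadata`.
#' @export
run_pca <- function(values, n_components = NULL, sample_metadata = NULL) {
  if (anyNA(values)) {
    stopf("missing values in input; run build_matrix (which imputes) first")
  }
  max_k <- min(ncol(values), nrow(values))
  k <- n_components %||% max_k
  if (k > max_k) {
    stopf("n_components (%d) exceeds min(n_samples, n_features) = %d", k, max_k)
  }
  pc <- stats::prcomp(t(values), center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  evr <- if (total_var > 0) pc$sdev^2 / total_var else rep(0, length(pc$sdev))
  k <- min(k, ncol(pc$rotation))
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- colnames(values)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = unname(evr[seq_len(k)]),
                 feature_ids = rownames(values),
                 sample_metadata = sample_metadata),
            class = "meth_pca")
}

#' @export
print.meth_pca <- function(x, ...) {
  cat(sprintf("PCA: %d samples x %d features, %d components\n",
              nrow(x$scores), length(x$feature_ids), ncol(x$scores)))
  cat("explained variance ratio:",
      paste(sprintf("%.3f", utils::head(x$explained_variance_ratio, 6)),
            collapse = " "), "\n")
  invisible(x)
}

# k-means++ seeding: spread initial centers with probability proportional
# to squared distance from the nearest chosen center.
kmeanspp_centers <- function(values, k) {
  n <- nrow(values)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(values, 2, values[centers[1], ])^2)
  for (j in seq_len(k - 1L)) {
    centers[j + 1L] <- if (sum(d2) > 0) {
      sample.int(n, 1L, prob = d2)
    } else {
      sample(setdiff(seq_len(n), centers[seq_len(j)]), 1L)
    }
    d2 <- pmin(d2, rowSums(sweep(values, 2, values[centers[j + 1L], ])^2))
  }
  values[centers, , drop = FALSE]
}

#' Cluster matrix rows with k-means
#'
#' k-means++ initialization, best of `n_restarts` by total within-cluster
#' sum of squares; labels renumbered by descending cluster size (ties by
#' first occurrence) so output is deterministic for a given seed.
#'
#' @param values Features x samples matrix; rows are clustered.
#' @param k Number of clusters (default 10).
#' @param seed Integer seed (RNG state of the caller is restored).
#' @param n_restarts Restarts (default 10).
#' @return Integer vector of cluster labels (1 = largest cluster), named by
#'   row names.
#' @export
kmeans_rows <- function(values, k = 10L, seed = 1L, n_restarts = 10L) {
  if (k > nrow(values)) {
    stopf("k (%d) exceeds the number of features (%d)", k, nrow(values))
  }
  if (k == nrow(values)) {
    # saturated case: every feature its own cluster, zero scatter
    labels <- seq_len(k)
    names(labels) <- rownames(values)
    return(labels)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      km <- suppressWarnings(
        stats::kmeans(values, centers = kmeanspp_centers(values, k),
                      iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  sizes <- tabulate(best$cluster, nbins = k)
  relabel <- integer(k)
  relabel[order(-sizes, seq_len(k))] <- seq_len(k)
  labels <- relabel[best$cluster]
  names(labels) <- rownames(values)
  labels
}

#' Select top-loading features of one component
#'
#' Partitions features by signed loading against `±threshold` (boundary
#' inclusive); features strictly inside `(-threshold, +threshold)` are
#' excluded.
#'
#' @param result A `meth_pca` object.
#' @param pc_index Component index.
#' @param threshold Positive loading cutoff (default 2.5e-2).
#' @return Object of class `dmr_selection`: `pc_index`, `threshold`,
#'   `positive_ids`, `negative_ids`.
#' @export
select_by_loading <- function(result, pc_index, threshold = 2.5e-2) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stopf("threshold must be positive")
  }
  if (pc_index < 1L || pc_index > ncol(result$loadings)) {
    stopf("pc_index %d outside 1..%d", pc_index, ncol(result$loadings))
  }
  v <- result$loadings[, pc_index]
  structure(list(pc_index = pc_index, threshold = threshold,
                 positive_ids = result$feature_ids[v >= threshold],
                 negative_ids = result$feature_ids[v <= -threshold]),
            class = "dmr_selection")
}

#' Per-component separation of two sample classes
#'
#' For each component, the two-class AUC of its score (rank statistic with
#' mid-ranks for ties), folded as `max(AUC, 1 - AUC)` so that 0.5 means no
#' separation and 1.0 perfect separation.
#'
#' @param scores Samples x components score matrix.
#' @param labels Logical (or two-level) vector per sample; `TRUE` is the
#'   positive class.
#' @return Named numeric vector of folded AUCs, one per component.
#' @export
separation_score <- function(scores, labels) {
  if (is.factor(labels) || is.character(labels)) {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) != 2L) stopf("labels must have exactly two classes")
    labels <- as.character(labels) == lev[2]
  }
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("both label classes must be present")
  apply(scores, 2, function(s) {
    r <- rank(s)
    auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    max(auc, 1 - auc)
  })
}
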