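#' Principal component analysis of a descriptor matrix
#'
#' Mean-centred (unscaled) PCA via the singular value decomposition; the
#' projection maximizing retained variance.  The explained-variance ratios
#' are reported against the total variance of the full descriptor matrix.
#'
#' @param descriptors numeric matrix, one row per frame (see
#'   [build_descriptors()]).
#' @param n_components number of components to keep (default 2: a 2D map is
#'   what the downstream state assignment works in).
#' @return object of class `cluster_model` (partially filled) with `scores`
#'   (frames x components), `rotation`, `center`,
#'   `explained_variance_ratio` and `n_components`.
#' @export
fit_pca <- function(descriptors, n_components = 2L) {
  X <- as.matrix(descriptors)
  if (nrow(X) < 2) stop("insufficient data: need at least 2 frames")
  if (n_components < 1 || n_components > min(dim(X)))
    stop("n_components must be in 1..min(n_frames, n_columns)")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x[, seq_len(n_components), drop = FALSE],
                 rotation = pr$rotation[, seq_len(n_components), drop = FALSE],
                 center = pr$center,
                 explained_variance_ratio = evr[seq_len(n_components)],
                 n_components = as.integer(n_components)),
            class = "cluster_model")
}

# greedy spread-out (k-means++) seeding in score space
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      idx[j] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ])^2))
    }
  }
  X[idx, , drop = FALSE]
}

#' K-means partition of PCA scores
#'
#' Lloyd-type k-means (via [stats::kmeans()]) started from greedy
#' spread-out (k-means++) seeds, with `n_init` restarts under one master
#' seed; the restart with the lowest within-cluster sum of squares wins, so
#' a fixed seed gives a deterministic partition.
#'
#' @param scores numeric matrix of component coordinates (frames x dims) or
#'   a `cluster_model` from [fit_pca()].
#' @param k number of clusters (1 <= k <= n frames).
#' @param seed master RNG seed.
#' @param n_init number of seeding restarts.
#' @return if `scores` is a `cluster_model`, the model completed with
#'   `k`, `labels`, `centroids`, `wcss`, `representatives` and `density`;
#'   otherwise a list with `labels`, `centroids`, `wcss`.
#' @export
kmeans_partition <- function(scores, k, seed = 1L, n_init = 10L) {
  model <- NULL
  if (inherits(scores, "cluster_model")) {
    model <- scores
    scores <- model$scores
  }
  X <- as.matrix(scores)
  n <- nrow(X)
  if (k < 1) stop("invalid k: must be >= 1")
  if (k > n) stop(sprintf("invalid k: %d clusters requested for %d frames", k, n))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    init <- .kmeanspp_init(X, k)
    km <- suppressWarnings(
      kmeans(X, centers = init, iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  out <- list(labels = as.integer(best$cluster),
              centroids = unname(best$centers),
              wcss = best$tot.withinss)
  if (is.null(model)) return(out)
  model$k <- as.integer(k)
  model$labels <- out$labels
  model$centroids <- out$centroids
  model$wcss <- out$wcss
  model$representatives <- select_representatives(model)
  model$density <- cluster_density(model)
  model
}

#' Representative frame of each cluster
#'
#' Per cluster, the member frame whose score is nearest (Euclidean, in
#' component space) to the cluster centroid; ties are broken towards the
#' lowest frame index.  An empty cluster yields `NA` with a warning.
#'
#' @param model a fitted `cluster_model` (labels and centroids present).
#' @return integer vector, one frame index per cluster.
#' @export
select_representatives <- function(model) {
  stopifnot(!is.null(model$labels), !is.null(model$centroids))
  k <- nrow(model$centroids)
  reps <- rep(NA_integer_, k)
  for (c in seq_len(k)) {
    mem <- which(model$labels == c)
    if (!length(mem)) {
      warning(sprintf("cluster %d is empty; representative set to NA", c))
      next
    }
    d2 <- rowSums(sweep(model$scores[mem, , drop = FALSE], 2,
                        model$centroids[c, ])^2)
    reps[c] <- mem[which.min(d2)]   # which.min takes the first = lowest index
  }
  reps
}

#' Fraction of frames assigned to each cluster
#'
#' @param model a fitted `cluster_model`.
#' @return numeric vector of length k summing to 1.
#' @export
cluster_density <- function(model) {
  stopifnot(!is.null(model$labels))
  tabulate(model$labels, nbins = nrow(model$centroids)) / length(model$labels)
}

#' Visit order of clusters along the simulation timeline
#'
#' Representative frames sorted by frame time: the order in which the
#' identified conformational states appear along the trajectory.
#'
#' @param model a fitted `cluster_model`.
#' @param frame_times frame times, ps (one per frame).
#' @return data.frame (`time`, `cluster`, `frame`) ordered by time; empty
#'   clusters are omitted.
#' @export
transition_timeline <- function(model, frame_times) {
  reps <- model$representatives %||% select_representatives(model)
  keep <- which(!is.na(reps))
  out <- data.frame(time = frame_times[reps[keep]], cluster = keep,
                    frame = reps[keep])
  out[order(out$time), , drop = FALSE]
}

#' One-call conformational-state discovery
#'
#' PCA of the descriptors followed by a k-means partition of the scores:
#' the standard pipeline for turning a trajectory into a small set of
#' conformational states with representative frames.
#'
#' @inheritParams fit_pca
#' @inheritParams kmeans_partition
#' @export
cluster_conformations <- function(descriptors, n_components = 2L, k = 7L,
                                  seed = 1L) {
  kmeans_partition(fit_pca(descriptors, n_components), k = k, seed = seed)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Conformational cluster model: %d frames, %d component(s)\n",
              nrow(x$scores), x$n_components))
  cat(sprintf("  explained variance ratio: %s\n",
              paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", ")))
  if (!is.null(x$k)) {
    ord <- order(x$density, decreasing = TRUE)
    cat(sprintf("  k = %d clusters (density-ordered): %s\n", x$k,
                paste(sprintf("#%d %.1f%%", ord, 100 * x$density[ord]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Export a cluster-model summary as JSON (plus labels CSV)
#'
#' @param model a fitted `cluster_model`.
#' @param path output JSON file; labels go to `<path without .json>_labels.csv`.
#' @export
write_cluster_summary <- function(model, path) {
  js <- list(n_components = model$n_components,
             explained_variance_ratio = model$explained_variance_ratio,
             k = model$k,
             density = model$density,
             representatives = model$representatives,
             wcss = model$wcss)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  labels_path <- sub("\\.json$", "", path)
  utils::write.csv(data.frame(frame = seq_along(model$labels),
                              cluster = model$labels),
                   paste0(labels_path, "_labels.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
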