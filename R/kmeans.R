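#' Initialize K-means cluster centers
#'
#' Two strategies. `"random"` samples `c` data points without replacement.
#' `"farthest"` is deterministic: the first center is the point nearest the
#' data mean, and each subsequent center is the point maximizing its minimum
#' Euclidean distance to the centers already chosen — centers placed as far
#' from each other as possible.
#'
#' @param points numeric matrix, one row per data point.
#' @param c number of cluster centers.
#' @param method `"farthest"` (default) or `"random"`.
#' @param seed optional integer seed (random method).
#' @return `c x ncol(points)` matrix of initial centroids.
#' @export
init_centroids <- function(points, c, method = c("farthest", "random"),
                           seed = NULL) {
  method <- match.arg(method)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < c) stop("cannot place ", c, " centers with only ", n, " points")
  if (method == "random") {
    idx <- local_seed(seed, sample.int(n, c))
    return(points[idx, , drop = FALSE])
  }
  # farthest-apart: greedy max-min distance, seeded at the mean-nearest point
  mu <- colMeans(points)
  first <- which.min(rowSums(sweep(points, 2L, mu)^2))
  chosen <- first
  mind <- rowSums(sweep(points, 2L, points[first, ])^2)
  while (length(chosen) < c) {
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, rowSums(sweep(points, 2L, points[nxt, ])^2))
  }
  points[chosen, , drop = FALSE]
}

#' Assign points to their nearest centroid
#'
#' Each point goes to the centroid at minimum Euclidean distance; ties
#' resolve to the lowest cluster index.
#'
#' @param points `n x d` matrix.
#' @param centroids `c x d` matrix.
#' @return object of class `"km_assignment"`: list with `cluster` (integer
#'   vector of 1-based indices) and `sizes` (points per cluster).
#' @export
km_assign <- function(points, centroids) {
  points <- as.matrix(points); centroids <- as.matrix(centroids)
  if (ncol(points) != ncol(centroids))
    stop("dimension mismatch: points have ", ncol(points),
         " features, centroids ", ncol(centroids))
  d2 <- cross_dist2(points, centroids)
  cluster <- max.col(-d2, ties.method = "first")
  structure(list(cluster = cluster,
                 sizes = tabulate(cluster, nbins = nrow(centroids))),
            class = "km_assignment")
}

# squared Euclidean cross-distance matrix, n x c
cross_dist2 <- function(points, centroids) {
  # computed termwise (not via the expanded |x|^2 - 2xy + |v|^2 identity)
  # so that exactly equidistant points tie exactly in floating point
  n <- nrow(points); k <- nrow(centroids)
  d2 <- matrix(0, n, k)
  for (j in seq_len(k)) {
    d2[, j] <- rowSums(sweep(points, 2L, centroids[j, ])^2)
  }
  d2
}

#' K-means objective: within-cluster sum of squared distances
#'
#' `J(V) = sum_i sum_{x in cluster i} ||x - v_i||^2` — zero exactly when
#' every point sits on its centroid.
#'
#' @param points `n x d` matrix.
#' @param centroids `c x d` matrix.
#' @param assignment a [km_assign()] result (or integer cluster vector).
#' @return non-negative scalar.
#' @export
km_objective <- function(points, centroids, assignment) {
  cluster <- if (inherits(assignment, "km_assignment")) assignment$cluster
             else as.integer(assignment)
  points <- as.matrix(points)
  sum((points - centroids[cluster, , drop = FALSE])^2)
}

#' Recompute centroids as within-cluster means
#'
#' Each new center is the arithmetic mean of its assigned points
#' (`v_i = (1/c_i) * sum x`). A cluster left empty by the assignment is
#' re-seeded at the point farthest from its nearest surviving centroid (the
#' worst-served point), with a message.
#'
#' @param points `n x d` matrix.
#' @param assignment a [km_assign()] result (or integer cluster vector).
#' @param c number of clusters.
#' @return `c x d` centroid matrix.
#' @export
update_centroids <- function(points, assignment, c) {
  cluster <- if (inherits(assignment, "km_assignment")) assignment$cluster
             else as.integer(assignment)
  points <- as.matrix(points)
  sizes <- tabulate(cluster, nbins = c)
  cent <- matrix(NA_real_, c, ncol(points))
  filled <- which(sizes > 0L)
  sums <- rowsum(points, cluster)
  cent[filled, ] <- sums / sizes[filled]
  empty <- which(sizes == 0L)
  if (length(empty)) {
    message("re-seeding ", length(empty), " empty cluster(s) at the ",
            "worst-served point")
    for (i in empty) {
      mind <- do.call(pmin, lapply(which(!is.na(cent[, 1L])), function(j)
        rowSums(sweep(points, 2L, cent[j, ])^2)))
      cent[i, ] <- points[which.max(mind), ]
    }
  }
  cent
}

#' Fit K-means by alternating assignment and centroid update
#'
#' Starting from [init_centroids()], alternates nearest-centroid assignment
#' and mean update until no data point is reassigned (the convergence rule)
#' or `max_iter` is reached. The objective `J` is recorded after each
#' assignment and is non-increasing across iterations.
#'
#' @param points `n x d` matrix of data points (pixel spectra).
#' @param c number of cluster centers (2 for cancer / non-cancer).
#' @param init `"farthest"` (default) or `"random"`.
#' @param seed optional integer seed (random init).
#' @param max_iter iteration cap (default 300).
#' @param wavelengths optional band centers stored on the model for
#'   interpretability.
#' @return list with `model` (class `"cluster_model"`: `centroids`, `c`,
#'   `wavelengths`) and `trace` (class `"km_trace"`: data.frame with
#'   `iteration`, `J`, `n_reassigned`, plus attributes `converged` and
#'   `iterations`).
#' @export
km_fit <- function(points, c, init = c("farthest", "random"), seed = NULL,
                   max_iter = 300L, wavelengths = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < c)
    stop("need at least c = ", c, " points; got ", nrow(points))
  if (max_iter < 1L) stop("max_iter must be >= 1")
  centroids <- init_centroids(points, c, method = match.arg(init),
                              seed = seed)
  prev <- NULL
  J <- numeric(0); reass <- integer(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    a <- km_assign(points, centroids)
    J[iter] <- km_objective(points, centroids, a)
    reass[iter] <- if (is.null(prev)) nrow(points)
                   else sum(a$cluster != prev$cluster)
    if (reass[iter] == 0L) { converged <- TRUE; break }
    centroids <- update_centroids(points, a, c)
    prev <- a
  }
  trace <- data.frame(iteration = seq_along(J), J = J, n_reassigned = reass)
  attr(trace, "converged") <- converged
  attr(trace, "iterations") <- length(J)
  class(trace) <- c("km_trace", "data.frame")
  model <- structure(list(centroids = centroids, c = c,
                          wavelengths = wavelengths),
                     class = "cluster_model")
  list(model = model, trace = trace)
}

#' Classify points with a trained cluster model
#'
#' Pure nearest-centroid assignment with the trained centers; no update, so
#' repeated calls are identical.
#'
#' @param model a `"cluster_model"` from [km_fit()].
#' @param points `n x d` matrix.
#' @return a [km_assign()] result.
#' @export
km_predict <- function(model, points) {
  km_assign(points, model$centroids)
}

#' Write centroids (with wavelength header) as TSV
#' @param model a `"cluster_model"`.
#' @param path output path.
#' @return invisibly, the data.frame written.
#' @export
write_centroids_tsv <- function(model, path) {
  df <- as.data.frame(model$centroids)
  names(df) <- if (!is.null(model$wavelengths))
    paste0("nm_", format(model$wavelengths, trim = TRUE))
  else paste0("feature_", seq_len(ncol(df)))
  df <- cbind(cluster = seq_len(nrow(df)), df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d centers x %d features\n",
              nrow(x$centroids), ncol(x$centroids)))
  invisible(x)
}
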