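# K-means partitioning of the feature space. Written in-package because the
# pipeline pins behaviours a generic implementation leaves open: k-means++
# seeding deterministic in one integer seed, nearest-centroid ties to the
# lowest cluster index, empty-cluster repair by farthest point, and a
# canonical cluster order (ascending centroid W) so cluster numbers are
# reproducible across runs.

.squared_dists <- function(points, centers) {
  # N x K matrix of squared Euclidean distances
  pp <- rowSums(points^2)
  cc <- rowSums(centers^2)
  outer(pp, cc, "+") - 2 * points %*% t(centers)
}

.kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  first <- sample.int(n, 1L)
  centers[1L, ] <- points[first, ]
  if (k > 1L) {
    d2 <- .squared_dists(points, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2:k) {
      d2 <- pmax(d2, 0)
      idx <- if (sum(d2) <= 0) sample.int(n, 1L) else
        sample.int(n, 1L, prob = d2)
      centers[j, ] <- points[idx, ]
      d2 <- pmin(d2, .squared_dists(points, centers[j, , drop = FALSE])[, 1L])
    }
  }
  centers
}

.assign_nearest <- function(points, centers) {
  d2 <- .squared_dists(points, centers)
  # ties -> lowest cluster index (max.col with ties.method = "first" on -d2)
  max.col(-d2, ties.method = "first")
}

.lloyd <- function(points, k, max_iter, tol) {
  centers <- .kmeanspp_init(points, k)
  assign_prev <- rep(0L, nrow(points))
  sse_prev <- Inf
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    assign_cur <- .assign_nearest(points, centers)
    # empty-cluster repair: move the globally farthest point into the gap
    repeat {
      sizes <- tabulate(assign_cur, nbins = k)
      empty <- which(sizes == 0L)
      if (!length(empty)) break
      d2 <- .squared_dists(points, centers)
      cur <- d2[cbind(seq_len(nrow(points)), assign_cur)]
      donor_ok <- sizes[assign_cur] > 1L
      cur[!donor_ok] <- -Inf
      far <- which.max(cur)
      centers[empty[1L], ] <- points[far, ]
      assign_cur[far] <- empty[1L]
    }
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- assign_cur == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(points[members, , drop = FALSE])
      }
    }
    d2 <- .squared_dists(points, new_centers)
    sse <- sum(d2[cbind(seq_len(nrow(points)), assign_cur)])
    if (sse > sse_prev + 1e-9) {
      stop("internal error: Lloyd iteration increased SSE", call. = FALSE)
    }
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    converged <- identical(assign_cur, assign_prev) || shift < tol ||
      iterations >= max_iter
    assign_prev <- assign_cur
    sse_prev <- sse
    if (converged) break
  }
  # final assignment consistent with final centers
  assign_final <- .assign_nearest(points, centers)
  list(assignments = assign_final, centers = centers,
       sse = sum(.squared_dists(points, centers)[
         cbind(seq_len(nrow(points)), assign_final)]),
       iterations = iterations)
}

#' K-means partition of a feature matrix
#'
#' Lloyd's algorithm with k-means++ seeding, best of `restarts` runs by
#' total SSE, deterministic given `seed`. Nearest-centroid ties go to the
#' lowest cluster index; an emptied cluster is repaired by reassigning the
#' point farthest from its centroid. Clusters are finally relabeled by
#' ascending centroid first coordinate (W), so cluster numbers are
#' reproducible across runs and seeds.
#'
#' @param features A `feature_matrix`, data frame with `W`/`H`(/`E`)
#'   columns, or numeric matrix.
#' @param k Number of clusters (default 4, the study setting),
#'   `1 <= k <= N`.
#' @param seed Integer seed for the restarts.
#' @param restarts Number of k-means++ restarts (default 50).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Centroid-shift convergence threshold (default 1e-10).
#' @return Object of class `kmeans_partition`: list with `k`,
#'   `assignments` (integer vector, canonical labels), `centroids`
#'   (`k x n` matrix), `sse_per_cluster`, `sse_total`, `iterations` (of the
#'   best restart), `restarts`, `seed`, `points`.
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 5), 20))
#' colnames(pts) <- c("W", "H")
#' kmeans_partition(pts, k = 2, seed = 1)
kmeans_partition <- function(features, k = 4L, seed = 1L, restarts = 50L,
                             max_iter = 300L, tol = 1e-10) {
  points <- feature_points(features)
  if (anyNA(points) || any(!is.finite(points))) {
    stop("features contain non-finite coordinates", call. = FALSE)
  }
  k <- as.integer(k)
  n <- nrow(points)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= N = ", n, call. = FALSE)
  best <- withr::with_seed(as.integer(seed), {
    best <- NULL
    for (r in seq_len(as.integer(restarts))) {
      run <- .lloyd(points, k, max_iter = max_iter, tol = tol)
      if (is.null(best) || run$sse < best$sse) best <- run
    }
    best
  })
  # canonical order: ascending centroid first coordinate
  ord <- order(best$centers[, 1L], seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  assignments <- relabel[best$assignments]
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("S", seq_len(k))
  colnames(centroids) <- colnames(points)
  sse_k <- vapply(seq_len(k), function(j) {
    members <- assignments == j
    sum(.squared_dists(points[members, , drop = FALSE],
                       centroids[j, , drop = FALSE]))
  }, numeric(1))
  structure(
    list(k = k, assignments = assignments, centroids = centroids,
         sse_per_cluster = sse_k, sse_total = sum(sse_k),
         iterations = best$iterations, restarts = as.integer(restarts),
         seed = as.integer(seed), points = points),
    class = "kmeans_partition"
  )
}

#' @export
print.kmeans_partition <- function(x, ...) {
  cat("K-means partition: K =", x$k, " N =", nrow(x$points),
      " total SSE =", signif(x$sse_total, 6), "\n")
  cat("  sizes:", paste(tabulate(x$assignments, x$k), collapse = ", "), "\n")
  cat("Centroids (canonical order, ascending W):\n")
  print(round(x$centroids, 4))
  invisible(x)
}

#' 1-of-K indicator matrix of a partition
#'
#' @param partition A `kmeans_partition`.
#' @return `N x K` binary matrix with exactly one 1 per row.
#' @export
indicator_matrix <- function(partition) {
  stopifnot(inherits(partition, "kmeans_partition"))
  n <- length(partition$assignments)
  m <- matrix(0L, n, partition$k,
              dimnames = list(rownames(partition$points),
                              rownames(partition$centroids)))
  m[cbind(seq_len(n), partition$assignments)] <- 1L
  m
}

#' Sum of squared errors of a partition
#'
#' Squared Euclidean distances of each point to its assigned centroid,
#' summed per cluster and in total.
#'
#' @param features Points (as in [kmeans_partition()]).
#' @param partition A `kmeans_partition` consistent with `features`, or a
#'   list with `assignments` and `centroids`.
#' @return List with `per_cluster` (numeric vector) and `total`.
#' @export
partition_sse <- function(features, partition) {
  points <- feature_points(features)
  assignments <- partition$assignments
  centroids <- partition$centroids
  if (length(assignments) != nrow(points)) {
    stop("partition has ", length(assignments), " assignments for ",
         nrow(points), " points", call. = FALSE)
  }
  k <- nrow(centroids)
  per <- vapply(seq_len(k), function(j) {
    members <- assignments == j
    if (!any(members)) return(0)
    sum(.squared_dists(points[members, , drop = FALSE],
                       centroids[j, , drop = FALSE]))
  }, numeric(1))
  list(per_cluster = per, total = sum(per))
}

#' SSE-versus-K selection report
#'
#' Best-of-restarts total SSE for each K in `k_range`; with enough
#' restarts the curve is non-increasing in K, and the elbow (largest
#' second difference) is a visual guide for choosing K. The configured
#' default K = 4 is flagged in the table.
#'
#' @param features Points (as in [kmeans_partition()]).
#' @param k_range Integer vector of K values within `[1, N]` (default 1:6).
#' @param seed Integer seed.
#' @param restarts Restarts per K (default 20).
#' @param default_k K value to flag (default 4).
#' @return Data frame with columns `k`, `sse`, `is_default`.
#' @export
k_selection_report <- function(features, k_range = 1:6, seed = 1L,
                               restarts = 20L, default_k = 4L) {
  points <- feature_points(features)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L) || any(k_range > nrow(points))) {
    stop("k_range must lie within [1, N]", call. = FALSE)
  }
  sse <- vapply(k_range, function(k) {
    kmeans_partition(points, k = k, seed = seed, restarts = restarts)$sse_total
  }, numeric(1))
  data.frame(k = k_range, sse = sse, is_default = k_range == default_k)
}
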