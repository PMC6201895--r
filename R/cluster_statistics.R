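# Inter- and intra-cluster statistics: centroids, Euclidean centroid
# distances, dispersion, covariance/correlation, trace-log-det (TLD)
# divergence and distance between cluster covariances, the
# information-theoretic metric (ITM) of a covariance against the identity,
# eigen-features, and Graham's-scan convex hulls for 2-dim clusters.
# Natural logarithms throughout.

.check_spd <- function(sigma, name = "matrix") {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma)) {
    stop(name, " must be square", call. = FALSE)
  }
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop(name, " must be symmetric", call. = FALSE)
  }
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(name, " must be positive definite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  }
  invisible(ev)
}

#' Centroid of a point set
#'
#' @param points Numeric matrix, one point per row (non-empty).
#' @return Numeric vector, the component-wise mean.
#' @export
cluster_centroid <- function(points) {
  points <- feature_points(points)
  if (nrow(points) == 0L) stop("empty cluster has no centroid", call. = FALSE)
  colMeans(points)
}

#' Pairwise Euclidean distances between centroids
#'
#' @param centroids Numeric matrix, one centroid per row.
#' @return Symmetric matrix of Euclidean norms with zero diagonal.
#' @export
euclidean_distances <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 1L) stop("need at least one centroid", call. = FALSE)
  as.matrix(stats::dist(centroids))
}

#' Cluster dispersion
#'
#' The cluster standard deviation is the root mean squared distance of the
#' members to the centroid with the unbiased divisor `N_k - 1` (cluster
#' sizes are small, so the unbiased form matters); the per-dimension
#' version divides by `sqrt(n)` so clusters of different feature dimension
#' are comparable.
#'
#' @param points Numeric matrix of cluster members (`N_k >= 2`).
#' @return List with `sigma` and `sigma_bar` (`sigma / sqrt(n)`).
#' @export
cluster_dispersion <- function(points) {
  points <- feature_points(points)
  nk <- nrow(points)
  if (nk < 2L) stop("dispersion needs N_k >= 2 points", call. = FALSE)
  mu <- colMeans(points)
  sigma2 <- sum(sweep(points, 2, mu)^2) / (nk - 1)
  sigma <- sqrt(sigma2)
  list(sigma = sigma, sigma_bar = sigma / sqrt(ncol(points)))
}

#' Unbiased cluster covariance matrix
#'
#' @param points Numeric matrix of cluster members (`N_k >= 2`).
#' @return `n x n` symmetric positive semi-definite matrix (divisor
#'   `N_k - 1`).
#' @export
cluster_covariance <- function(points) {
  points <- feature_points(points)
  if (nrow(points) < 2L) stop("covariance needs N_k >= 2 points", call. = FALSE)
  stats::cov(points)
}

#' Correlation matrix from a covariance matrix
#'
#' Pearson normalization `Cr_ij = S_ij / sqrt(S_ii S_jj)`.
#'
#' @param covariance Symmetric matrix with strictly positive diagonal.
#' @return Correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(covariance) {
  covariance <- as.matrix(covariance)
  if (any(diag(covariance) <= 0)) {
    stop("zero or negative variance: correlation undefined", call. = FALSE)
  }
  stats::cov2cor(covariance)
}

#' Trace-log-det divergence between two covariance matrices
#'
#' `div_T(A, B) = (1/n) [tr(A B^-1) - ln det(A B^-1) - n]`, the per-
#' dimension Burg/Stein-type log-det divergence. Non-negative, zero iff
#' `A = B`, and asymmetric in its arguments. A singular second argument is
#' a domain error; no silent regularization is applied.
#'
#' @param sigma_k,sigma_i Symmetric positive definite matrices of equal
#'   dimension.
#' @return Non-negative scalar.
#' @export
#' @examples
#' tld_divergence(2 * diag(2), diag(2)) # 1 - log(2)
tld_divergence <- function(sigma_k, sigma_i) {
  sigma_k <- as.matrix(sigma_k); sigma_i <- as.matrix(sigma_i)
  .check_spd(sigma_k, "sigma_k")
  .check_spd(sigma_i, "sigma_i")
  if (nrow(sigma_k) != nrow(sigma_i)) {
    stop("matrices must have equal dimension", call. = FALSE)
  }
  n <- nrow(sigma_k)
  m <- solve(sigma_i, sigma_k)       # B^-1 A; tr and det equal those of A B^-1
  ld <- determinant(m, logarithm = TRUE)
  if (ld$sign <= 0) stop("log-determinant undefined (non-positive)", call. = FALSE)
  (sum(diag(m)) - as.numeric(ld$modulus) - n) / n
}

#' Trace-log-det distance between two covariance matrices
#'
#' Symmetrized average of the two [tld_divergence()] directions.
#'
#' @inheritParams tld_divergence
#' @return Non-negative scalar, zero iff the matrices are equal.
#' @export
#' @examples
#' tld_distance(2 * diag(2), diag(2)) # exactly 0.25
tld_distance <- function(sigma_k, sigma_i) {
  (tld_divergence(sigma_k, sigma_i) + tld_divergence(sigma_i, sigma_k)) / 2
}

#' Information-theoretic metric of a covariance matrix
#'
#' Divergence of a cluster covariance from the identity ("ideal") cluster:
#' in the `per_dimension` convention this is exactly
#' [tld_divergence()]`(sigma, I)`; the `unnormalized` convention (the
#' reporting default) omits the `1/n` factor:
#' `tr(sigma) - ln det(sigma) - n`. Both are non-negative and zero iff
#' `sigma = I`.
#'
#' @param sigma Symmetric positive definite matrix.
#' @param convention `"unnormalized"` (default) or `"per_dimension"`.
#' @return Non-negative scalar.
#' @export
#' @examples
#' itm(diag(2))                        # 0
#' itm(diag(c(2, 2)))                  # 2 - 2 log 2
#' itm(diag(c(2, 2)), "per_dimension") # 1 - log 2
itm <- function(sigma, convention = c("unnormalized", "per_dimension")) {
  convention <- match.arg(convention)
  sigma <- as.matrix(sigma)
  .check_spd(sigma, "sigma")
  n <- nrow(sigma)
  ld <- determinant(sigma, logarithm = TRUE)
  val <- sum(diag(sigma)) - as.numeric(ld$modulus) - n
  if (convention == "per_dimension") val / n else val
}

#' Eigen-decomposition of a cluster covariance
#'
#' Eigenvalues in decreasing order with orthonormal eigen-features (the
#' principal axes of the cluster). The sign of each eigen-feature is fixed
#' so that its largest-magnitude component is positive, making the output
#' reproducible.
#'
#' @param sigma Symmetric matrix (asymmetry beyond `1e-8` relative is a
#'   domain error).
#' @return List with `values` (decreasing) and `vectors` (columns are the
#'   eigen-features; `sigma = vectors %*% diag(values) %*% t(vectors)`).
#' @export
#' @examples
#' eigen_features(diag(c(3, 1, 2)))$values # 3 2 1
eigen_features <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma) ||
      max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop("sigma must be symmetric", call. = FALSE)
  }
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  v <- e$vectors
  for (j in seq_len(ncol(v))) {
    lead <- which.max(abs(v[, j]))
    if (v[lead, j] < 0) v[, j] <- -v[, j]
  }
  list(values = e$values, vectors = v)
}

#' Convex hull of a 2-dim point set by Graham's scan
#'
#' Returns the hull vertices in counter-clockwise order starting from the
#' lowest-y (then lowest-x) point; collinear boundary points are excluded.
#' Fewer than 3 points, or an all-collinear set, is a degenerate hull: the
#' extreme points are returned with attribute `degenerate = TRUE`.
#'
#' @param points Numeric matrix with 2 columns.
#' @return Matrix of hull vertices (rows, in CCW order); attribute
#'   `degenerate` is `TRUE` for degenerate input.
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
#' graham_scan(sq) # the four corners
graham_scan <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("graham_scan needs 2-dim points", call. = FALSE)
  points <- unique(points)
  n <- nrow(points)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  degenerate <- function(pts) {
    out <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
    out <- out[c(1L, nrow(out)), , drop = FALSE]
    out <- unique(out)
    attr(out, "degenerate") <- TRUE
    out
  }
  if (n < 3L) return(degenerate(points))
  # pivot: lowest y, then lowest x
  pivot_idx <- order(points[, 2], points[, 1])[1]
  pivot <- points[pivot_idx, ]
  rest <- points[-pivot_idx, , drop = FALSE]
  ang <- atan2(rest[, 2] - pivot[2], rest[, 1] - pivot[1])
  d <- sqrt((rest[, 1] - pivot[1])^2 + (rest[, 2] - pivot[2])^2)
  rest <- rest[order(ang, d), , drop = FALSE]
  stack <- list(pivot)
  for (i in seq_len(nrow(rest))) {
    p <- rest[i, ]
    while (length(stack) >= 2L &&
           cross(stack[[length(stack) - 1L]], stack[[length(stack)]], p) <= 1e-12 * max(1, sum(abs(p)))) {
      stack[[length(stack)]] <- NULL
    }
    stack[[length(stack) + 1L]] <- p
  }
  hull <- do.call(rbind, stack)
  if (nrow(hull) < 3L) return(degenerate(points))
  colnames(hull) <- colnames(points)
  attr(hull, "degenerate") <- FALSE
  hull
}

#' Full cluster-statistics report for a partition
#'
#' Computes, per cluster: size, centroid, dispersion (`sigma`,
#' `sigma_bar`), covariance, correlation, eigenvalues and eigen-features,
#' the ITM in both conventions, per-cluster SSE, and (for 2-dim features)
#' the convex-hull vertices. Pairwise across clusters: the Euclidean
#' centroid-distance matrix and the TLD divergence (asymmetric) and
#' distance (symmetric) matrices.
#'
#' @param features Points (as in [kmeans_partition()]).
#' @param partition A [kmeans_partition()] of those points.
#' @return Object of class `cluster_statistics`.
#' @export
cluster_statistics <- function(features, partition) {
  stopifnot(inherits(partition, "kmeans_partition"))
  points <- feature_points(features)
  if (nrow(points) != length(partition$assignments)) {
    stop("features and partition disagree on N", call. = FALSE)
  }
  k <- partition$k
  ndim <- ncol(points)
  members <- lapply(seq_len(k), function(j) {
    points[partition$assignments == j, , drop = FALSE]
  })
  per_cluster <- lapply(seq_len(k), function(j) {
    pts <- members[[j]]
    if (nrow(pts) < 2L) {
      warning("cluster ", j, " has fewer than 2 members; ",
              "second-order statistics unavailable", call. = FALSE)
      return(list(size = nrow(pts), centroid = cluster_centroid(pts)))
    }
    sig <- cluster_covariance(pts)
    disp <- cluster_dispersion(pts)
    ef <- eigen_features(sig)
    spd <- min(ef$values) > 0
    list(size = nrow(pts),
         centroid = cluster_centroid(pts),
         sigma = disp$sigma, sigma_bar = disp$sigma_bar,
         covariance = sig,
         correlation = if (all(diag(sig) > 0)) correlation_matrix(sig) else NULL,
         eigenvalues = ef$values, eigen_features = ef$vectors,
         itm_unnormalized = if (spd) itm(sig, "unnormalized") else NA_real_,
         itm_per_dimension = if (spd) itm(sig, "per_dimension") else NA_real_,
         hull = if (ndim == 2L && nrow(pts) >= 3L) graham_scan(pts) else NULL)
  })
  names(per_cluster) <- rownames(partition$centroids)
  sse <- partition_sse(points, partition)
  covs <- lapply(per_cluster, `[[`, "covariance")
  have_spd <- vapply(seq_len(k), function(j) {
    !is.null(covs[[j]]) && !is.na(per_cluster[[j]]$itm_unnormalized)
  }, logical(1))
  div_m <- matrix(NA_real_, k, k, dimnames = list(names(per_cluster),
                                                  names(per_cluster)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (have_spd[a] && have_spd[b]) {
      div_m[a, b] <- if (a == b) 0 else tld_divergence(covs[[a]], covs[[b]])
    }
  }
  dist_m <- (div_m + t(div_m)) / 2
  structure(
    list(k = k, dim = ndim,
         per_cluster = per_cluster,
         euclidean = euclidean_distances(partition$centroids),
         tld_divergence = div_m,
         tld_distance = dist_m,
         sse_per_cluster = sse$per_cluster,
         sse_total = sse$total),
    class = "cluster_statistics"
  )
}

#' @export
print.cluster_statistics <- function(x, ...) {
  cat("Cluster statistics:", x$k, "clusters in", x$dim, "dimensions\n")
  tab <- do.call(rbind, lapply(x$per_cluster, function(pc) {
    data.frame(size = pc$size,
               sigma = if (is.null(pc$sigma)) NA else round(pc$sigma, 4),
               itm = if (is.null(pc$itm_unnormalized)) NA else
                 round(pc$itm_unnormalized, 4))
  }))
  print(tab)
  cat("total SSE:", signif(x$sse_total, 4), "\n")
  invisible(x)
}
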