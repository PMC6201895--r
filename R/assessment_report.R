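# Qualitative assessment: per-factor cluster ranks (High / Moderate / Low /
# Bottom), the overall four-level quality assignment, expert-style
# three-band labels, and the machine-readable pipeline report.

.rank_names <- c("High", "Moderate", "Low", "Bottom")
.level_names <- c("Excellent", "Good", "Moderate", "Unqualified")

#' Per-factor qualitative cluster labels
#'
#' Ranks K = 4 clusters on each intrinsic factor from their 3-dim centroids:
#' attention span by descending centroid W, attention stability by
#' descending centroid H, and distribution-shift by ascending centroid E
#' (a low error rate means rapid and exact attention switching, hence
#' "High"). Ranks 1..4 map to High, Moderate, Low, Bottom. Ties are broken
#' by cluster index and flagged.
#'
#' For K other than 4 the numeric ranks are reported without the four-name
#' mapping.
#'
#' @param centroids `K x 3` matrix of cluster centroids, columns `[W, H, E]`.
#' @return Object of class `factor_labels`: data frame with columns
#'   `cluster`, `span`, `stability`, `distribution_shift` (character labels
#'   for K = 4, integer ranks otherwise); attribute `ties` flags tied
#'   centroids.
#' @export
#' @examples
#' ctr <- rbind(c(0.27, 0.60, 0.05), c(0.58, 0.67, 0.07),
#'              c(0.40, 0.67, 0.59), c(0.66, 0.65, 0.86))
#' rank_factor_labels(ctr)
rank_factor_labels <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 3L) {
    stop("rank_factor_labels needs 3-dim centroids [W, H, E]", call. = FALSE)
  }
  k <- nrow(centroids)
  rank_desc <- function(v) rank(-v, ties.method = "first")
  rank_asc <- function(v) rank(v, ties.method = "first")
  ties <- anyDuplicated(centroids[, 1]) > 0 ||
    anyDuplicated(centroids[, 2]) > 0 || anyDuplicated(centroids[, 3]) > 0
  if (ties) {
    warning("tied centroid coordinates: ranks broken by cluster index",
            call. = FALSE)
  }
  ranks <- data.frame(
    cluster = if (!is.null(rownames(centroids))) rownames(centroids)
              else paste0("S", seq_len(k)),
    span = rank_desc(centroids[, 1]),
    stability = rank_desc(centroids[, 2]),
    distribution_shift = rank_asc(centroids[, 3])
  )
  out <- ranks
  if (k == 4L) {
    out$span <- .rank_names[ranks$span]
    out$stability <- .rank_names[ranks$stability]
    out$distribution_shift <- .rank_names[ranks$distribution_shift]
  }
  rownames(out) <- NULL
  structure(out, ranks = ranks, ties = ties,
            class = c("factor_labels", "data.frame"))
}

#' Overall four-level quality assignment
#'
#' The composite score of a cluster is the sum of its three factor ranks
#' (1 = High ... 4 = Bottom); ascending score maps to Level 1..4 with names
#' Excellent, Good, Moderate, Unqualified. Score ties are broken by
#' ascending centroid E (lower error rate wins). Invariant to cluster
#' relabeling.
#'
#' @param labels A [rank_factor_labels()] result.
#' @param centroids The same `K x 3` centroid matrix (used for the E
#'   tie-break).
#' @return Data frame with columns `cluster`, `score`, `level`,
#'   `level_name`.
#' @export
assign_levels <- function(labels, centroids) {
  stopifnot(inherits(labels, "factor_labels"))
  centroids <- as.matrix(centroids)
  ranks <- attr(labels, "ranks")
  score <- ranks$span + ranks$stability + ranks$distribution_shift
  ord <- order(score, centroids[, 3])
  level <- integer(length(score))
  level[ord] <- seq_along(score)
  out <- data.frame(cluster = ranks$cluster, score = score, level = level,
                    level_name = if (length(score) == 4L)
                      .level_names[level] else as.character(level))
  rownames(out) <- NULL
  out
}

#' Expert-style three-band labels per participant
#'
#' Mirrors the structure of an expert 1-9 point grading collapsed to three
#' bands per factor: W maps to Narrow / Medium / Wide, H to Bad / Medium /
#' Good, and E (inverted: high error is bad) to Slow & Inaccurate / Medium /
#' Rapid & Exact. Default cut points are the cohort terciles of each
#' feature.
#'
#' @param features A 3-dim `feature_matrix` (columns `W`, `H`, `E`).
#' @param thresholds Optional list with numeric length-2 ascending cut
#'   points `W`, `H`, `E`; `NULL` (default) uses cohort terciles.
#' @return Data frame with columns `participant_id`, `span_band`,
#'   `stability_band`, `shift_band`.
#' @export
expert_threshold_labels <- function(features, thresholds = NULL) {
  stopifnot(is.data.frame(features), all(c("W", "H", "E") %in% names(features)))
  cuts_for <- function(v, nm) {
    cp <- if (is.null(thresholds)) {
      as.numeric(stats::quantile(v, c(1 / 3, 2 / 3)))
    } else {
      as.numeric(thresholds[[nm]])
    }
    if (length(cp) != 2L || cp[1] > cp[2]) {
      stop("thresholds for ", nm, " must be 2 non-decreasing cut points",
           call. = FALSE)
    }
    cp
  }
  band <- function(v, cp) 1L + (v > cp[1]) + (v > cp[2])
  cw <- cuts_for(features$W, "W")
  ch <- cuts_for(features$H, "H")
  ce <- cuts_for(features$E, "E")
  data.frame(
    participant_id = features$participant_id,
    span_band = c("Narrow", "Medium", "Wide")[band(features$W, cw)],
    stability_band = c("Bad", "Medium", "Good")[band(features$H, ch)],
    # inverted sense: a high error rate is the bad band
    shift_band = c("Rapid & Exact", "Medium",
                   "Slow & Inaccurate")[band(features$E, ce)]
  )
}

#' Assemble the full assessment report
#'
#' Bundles every table the pipeline produces for one run: features,
#' partition, cluster statistics, factor labels, levels, and the echoed
#' configuration. All numeric content comes from the supplied objects; no
#' re-computation happens here beyond shape checks.
#'
#' @param features `feature_matrix` used for clustering.
#' @param partition The [kmeans_partition()] of those features.
#' @param stats The [cluster_statistics()] of that partition.
#' @param labels A [rank_factor_labels()] result (or `NULL` in 2-dim runs).
#' @param levels An [assign_levels()] result (or `NULL` in 2-dim runs).
#' @return Object of class `assessment_report`.
#' @export
build_report <- function(features, partition, stats, labels = NULL,
                         levels = NULL) {
  stopifnot(inherits(partition, "kmeans_partition"),
            inherits(stats, "cluster_statistics"))
  if (nrow(features) != length(partition$assignments)) {
    stop("integrity error: features and partition disagree on N", call. = FALSE)
  }
  if (stats$k != partition$k) {
    stop("integrity error: stats and partition disagree on K", call. = FALSE)
  }
  structure(
    list(features = features,
         assignments = data.frame(
           participant_id = features$participant_id,
           cluster = rownames(partition$centroids)[partition$assignments]),
         centroids = partition$centroids,
         statistics = stats,
         factor_labels = labels,
         levels = levels,
         config = list(k = partition$k, seed = partition$seed,
                       restarts = partition$restarts,
                       feature_dim = attr(features, "feature_dim"),
                       bounds = attr(features, "bounds"))),
    class = "assessment_report"
  )
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("Assessment report:", nrow(x$features), "participants,",
      x$config$k, "clusters,", x$config$feature_dim, "features\n\n")
  cat("Centroids:\n"); print(round(x$centroids, 4))
  if (!is.null(x$factor_labels)) {
    cat("\nFactor labels:\n"); print(as.data.frame(x$factor_labels))
  }
  if (!is.null(x$levels)) {
    cat("\nLevels:\n"); print(x$levels)
  }
  cat("\nTotal SSE:", signif(x$statistics$sse_total, 4), "\n")
  invisible(x)
}

#' Run the whole assessment pipeline on a cohort
#'
#' Features, K-means partition, cluster statistics, factor labels and
#' levels (3-dim runs), assembled into one report.
#'
#' @param cohort An [ntt_cohort()].
#' @param dim Feature dimension (2 or 3; default 3).
#' @param k Number of clusters (default 4).
#' @param seed Integer seed for the clustering restarts.
#' @param rs_config An [rs_config()].
#' @param bounds_mode,bounds Passed to [extract_features()].
#' @param restarts K-means restarts (default 50).
#' @return An [build_report()] `assessment_report`.
#' @export
#' @examples
#' \donttest{
#' co <- generate_cohort(default_cohort_spec(seed = 1))
#' rep <- assess_cohort(co, dim = 3, seed = 1)
#' rep$levels
#' }
assess_cohort <- function(cohort, dim = 3L, k = 4L, seed = 1L,
                          rs_config = attnquality::rs_config(),
                          bounds_mode = c("cohort", "fixed"),
                          bounds = c(200, 800), restarts = 50L) {
  bounds_mode <- match.arg(bounds_mode)
  features <- extract_features(cohort, dim = dim, rs_config = rs_config,
                               bounds_mode = bounds_mode, bounds = bounds)
  partition <- kmeans_partition(features, k = k, seed = seed,
                                restarts = restarts)
  stats <- cluster_statistics(features, partition)
  labels <- NULL
  levels <- NULL
  if (as.integer(dim) == 3L && k == 4L) {
    labels <- rank_factor_labels(partition$centroids)
    levels <- assign_levels(labels, partition$centroids)
  }
  build_report(features, partition, stats, labels, levels)
}

#' Write an assessment report to disk
#'
#' Emits a machine-readable JSON report plus CSV tables (features with
#' cluster assignments, centroids, factor labels, levels) under `dir`.
#' Writing the same report twice produces byte-identical files.
#'
#' @param report An `assessment_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "assessment_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- report$statistics
  json <- list(
    config = report$config,
    centroids = report$centroids,
    sse = list(per_cluster = st$sse_per_cluster, total = st$sse_total),
    euclidean_distances = st$euclidean,
    tld_divergence = st$tld_divergence,
    tld_distance = st$tld_distance,
    clusters = lapply(st$per_cluster, function(pc) {
      list(size = pc$size, centroid = pc$centroid, sigma = pc$sigma,
           sigma_bar = pc$sigma_bar, covariance = pc$covariance,
           correlation = pc$correlation, eigenvalues = pc$eigenvalues,
           eigen_features = pc$eigen_features,
           itm_unnormalized = pc$itm_unnormalized,
           itm_per_dimension = pc$itm_per_dimension,
           hull = if (!is.null(pc$hull)) unclass(pc$hull) else NULL)
    }),
    factor_labels = if (!is.null(report$factor_labels))
      as.data.frame(report$factor_labels) else NULL,
    levels = report$levels
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor", null = "null")
  feat <- merge(report$features, report$assignments, by = "participant_id",
                sort = FALSE)
  utils::write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(cbind(cluster = rownames(report$centroids),
                         as.data.frame(report$centroids)),
                   file.path(dir, "centroids.csv"), row.names = FALSE)
  if (!is.null(report$factor_labels)) {
    utils::write.csv(as.data.frame(report$factor_labels),
                     file.path(dir, "factor_labels.csv"), row.names = FALSE)
  }
  if (!is.null(report$levels)) {
    utils::write.csv(report$levels, file.path(dir, "levels.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
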