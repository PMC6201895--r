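# Per-participant feature vectors [W, H] or [W, H, E]:
#   W — normalized number of decisions (attention span proxy),
#   H — Hurst exponent of the reaction-time series (stability proxy),
#   E — error rate of decisions (distribution-shift proxy).
# Only W needs normalization: H already lives in (0, 1) and E is a fraction.

#' Min-max normalization to \[0, 1\]
#'
#' Affine map sending the minimum to 0 and the maximum to 1.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' min_max_normalize(c(200, 500, 800))
min_max_normalize <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values contain NA", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    stop("degenerate scale: all values equal (", rng[1], ")", call. = FALSE)
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Normalized number of decisions (W)
#'
#' `W = (I - I_min) / (I_max - I_min)`, clipped to \[0, 1\] with a warning
#' when the NoD falls outside the bounds.
#'
#' @param nod Positive integer vector of decision counts.
#' @param bounds Length-2 numeric `(I_min, I_max)` with `I_max > I_min`;
#'   default the test design range `c(200, 800)`.
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' compute_nnod(c(200, 500, 800))
compute_nnod <- function(nod, bounds = c(200, 800)) {
  if (length(bounds) != 2L || bounds[2] <= bounds[1]) {
    stop("bounds must satisfy I_max > I_min", call. = FALSE)
  }
  w <- (as.numeric(nod) - bounds[1]) / (bounds[2] - bounds[1])
  out_of_range <- w < 0 | w > 1
  if (any(out_of_range)) {
    warning(sum(out_of_range), " NoD value(s) outside bounds [",
            bounds[1], ", ", bounds[2], "]; W clipped", call. = FALSE)
    w <- pmin(pmax(w, 0), 1)
  }
  w
}

#' Error rate of decisions (E)
#'
#' Fraction of events with `correct = FALSE` over all decisions, including
#' "Ignore" decisions (the denominator is the total number of decisions).
#' Stored as a fraction in \[0, 1\].
#'
#' @param sequence A [response_sequence()].
#' @return Numeric scalar in \[0, 1\].
#' @export
compute_erd <- function(sequence) {
  stopifnot(inherits(sequence, "response_sequence"))
  n <- nrow(sequence$events)
  if (n < 1L) stop("empty sequence has no error rate", call. = FALSE)
  mean(!sequence$events$correct)
}

#' Extract the feature matrix of a cohort
#'
#' Per participant: W from the NoD, H from R/S analysis of the concatenated
#' reaction-time sequence, and (for `dim = 3`) E from the correctness
#' flags. Row order equals cohort order. Component order is fixed as
#' `[W, H]` / `[W, H, E]`.
#'
#' @param cohort An [ntt_cohort()].
#' @param dim Feature dimension, 2 (`[W, H]`) or 3 (`[W, H, E]`).
#' @param rs_config An [rs_config()] controlling the Hurst estimation.
#' @param bounds_mode `"cohort"` (default) normalizes W by the cohort's
#'   min/max NoD; `"fixed"` uses `bounds`.
#' @param bounds Fixed normalization bounds for `bounds_mode = "fixed"`
#'   (default `c(200, 800)`, the test design range).
#' @return Data frame of class `feature_matrix` with columns
#'   `participant_id`, `W`, `H` and (if `dim = 3`) `E`; attributes
#'   `feature_dim`, `bounds` (the bounds actually used) and `dropped`
#'   (ids of participants whose Hurst estimation failed, excluded with a
#'   warning).
#' @export
extract_features <- function(cohort, dim = 3L, rs_config = attnquality::rs_config(),
                             bounds_mode = c("cohort", "fixed"),
                             bounds = c(200, 800)) {
  stopifnot(inherits(cohort, "ntt_cohort"))
  bounds_mode <- match.arg(bounds_mode)
  dim <- as.integer(dim)
  if (!dim %in% c(2L, 3L)) stop("dim must be 2 or 3", call. = FALSE)
  if (length(cohort$sequences) == 0L) stop("cohort is empty", call. = FALSE)

  nod <- n_decisions(cohort)
  if (bounds_mode == "cohort") {
    if (length(unique(nod)) < 2L) {
      stop("degenerate scale: cohort bounds need >= 2 distinct NoD values",
           call. = FALSE)
    }
    bounds <- range(nod)
  }
  w <- compute_nnod(nod, bounds)

  h <- vapply(cohort$sequences, function(s) {
    est <- tryCatch(estimate_hurst(reaction_times(s), rs_config),
                    error = function(e) NULL)
    if (is.null(est)) NA_real_ else est$H
  }, numeric(1))

  out <- data.frame(participant_id = participant_ids(cohort),
                    W = as.numeric(w), H = as.numeric(h))
  if (dim == 3L) {
    out$E <- vapply(cohort$sequences, compute_erd, numeric(1))
  }
  dropped <- out$participant_id[is.na(out$H)]
  if (length(dropped)) {
    warning("Hurst estimation failed for participant(s) ",
            paste(dropped, collapse = ", "), "; rows excluded", call. = FALSE)
    out <- out[!is.na(out$H), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, feature_dim = dim, bounds = bounds, dropped = dropped,
            class = c("feature_matrix", "data.frame"))
}

#' Numeric feature matrix of a feature table
#'
#' @param features A `feature_matrix` (from [extract_features()]) or any
#'   data frame with columns `W`, `H` and optionally `E`, or a plain
#'   numeric matrix (returned unchanged).
#' @return Numeric matrix with one row per participant, columns in the
#'   fixed `[W, H(, E)]` order.
#' @export
feature_points <- function(features) {
  if (is.matrix(features)) {
    storage.mode(features) <- "double"
    return(features)
  }
  stopifnot(is.data.frame(features))
  cols <- intersect(c("W", "H", "E"), names(features))
  if (!all(c("W", "H") %in% cols)) {
    stop("features must contain columns W and H", call. = FALSE)
  }
  m <- as.matrix(features[cols])
  rownames(m) <- if ("participant_id" %in% names(features)) {
    as.character(features$participant_id)
  } else NULL
  m
}
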