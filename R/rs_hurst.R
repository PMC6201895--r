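#' Configuration for rescaled-range (R/S) analysis
#'
#' Bundles the window schedule and regression settings used by [rs_curve()]
#' and [estimate_hurst()].
#'
#' @param window_sizes Increasing integer vector of window lengths `n`, or
#'   `NULL` (default) to build the dyadic schedule from the series length at
#'   analysis time (see [dyadic_windows()]). Every window must be at least 8
#'   and at most half the series length.
#' @param min_windows Minimum number of usable curve points required for the
#'   log-log regression; fewer is an estimation error. Must be `>= 3`.
#' @param correction Finite-sample bias handling for the regression:
#'   `"anis-lloyd"` (default) regresses the log R/S statistic against its
#'   exact i.i.d. expectation (Anis--Lloyd with the small-sample front
#'   factor) and recenters at 0.5, which removes the well-known upward bias
#'   of plain R/S on short series; `"none"` is the plain ordinary
#'   least-squares slope of `log (R/S)_n` on `log n`.
#' @return An object of class `rs_config`.
#' @seealso [estimate_hurst()], [rs_curve()]
#' @export
#' @examples
#' rs_config()
#' rs_config(window_sizes = c(8, 16, 32, 64), correction = "none")
rs_config <- function(window_sizes = NULL,
                      min_windows = 3L,
                      correction = c("anis-lloyd", "none")) {
  correction <- match.arg(correction)
  if (!is.null(window_sizes)) {
    window_sizes <- as.integer(window_sizes)
    if (anyNA(window_sizes) || any(window_sizes < 8L)) {
      stop("every window size must be an integer >= 8", call. = FALSE)
    }
    if (is.unsorted(window_sizes, strictly = TRUE)) {
      stop("window_sizes must be strictly increasing", call. = FALSE)
    }
  }
  min_windows <- as.integer(min_windows)
  if (is.na(min_windows) || min_windows < 3L) {
    stop("min_windows must be an integer >= 3", call. = FALSE)
  }
  structure(
    list(window_sizes = window_sizes, min_windows = min_windows,
         correction = correction),
    class = "rs_config"
  )
}

#' @export
print.rs_config <- function(x, ...) {
  cat("R/S analysis configuration\n")
  if (is.null(x$window_sizes)) {
    cat("  windows    : dyadic schedule (chosen per series)\n")
  } else {
    cat("  windows    :", paste(x$window_sizes, collapse = ", "), "\n")
  }
  cat("  min windows:", x$min_windows, "\n")
  cat("  correction :", x$correction, "\n")
  invisible(x)
}

#' Dyadic window schedule for R/S analysis
#'
#' Windows are `floor(l / 2^j)` for `j = 1, ...` down to `min_window`, plus
#' `min_window` itself, deduplicated and ascending. Logarithmically spaced
#' windows give evenly weighted points on the log-log regression.
#'
#' @param l Series length.
#' @param min_window Smallest window admitted (default 8).
#' @return Increasing integer vector of window sizes.
#' @export
#' @examples
#' dyadic_windows(1024)
dyadic_windows <- function(l, min_window = 8L) {
  l <- as.integer(l)
  min_window <- as.integer(min_window)
  if (l < 2L * min_window) {
    stop("series too short for any window: length ", l, call. = FALSE)
  }
  j_max <- floor(log2(l / min_window))
  w <- as.integer(c(l %/% 2^seq_len(j_max), min_window))
  sort(unique(w[w >= min_window]))
}

#' Segment a series into non-overlapping blocks
#'
#' Splits `x` into `d = floor(length(x) / n)` consecutive blocks of length
#' `n`; the trailing remainder is discarded.
#'
#' @param x Numeric vector.
#' @param n Block length, `2 <= n <= length(x)`.
#' @return List of `d` numeric vectors, each of length `n`.
#' @export
#' @examples
#' segment_series(1:11, 5) # two blocks, element 11 dropped
segment_series <- function(x, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2", call. = FALSE)
  if (n > length(x)) {
    stop("window n = ", n, " exceeds series length ", length(x), call. = FALSE)
  }
  d <- length(x) %/% n
  lapply(seq_len(d) - 1L, function(m) x[(m * n + 1L):((m + 1L) * n)])
}

#' Rescaled range of one block
#'
#' For a block of length `n`: the mean is removed, the deviations are
#' cumulated, and `R` is the range (max minus min) of the cumulative sums;
#' `S` is the unbiased standard deviation (divisor `n - 1`). A block with
#' `S = 0` (constant block) is degenerate and carries no R/S value.
#'
#' @param block Numeric vector of length `>= 2`.
#' @return List with components `R`, `S`, `rs` (`R/S`, `NA` when degenerate)
#'   and `degenerate` (logical).
#' @export
#' @examples
#' rescaled_range(c(1, 2, 3, 4))
rescaled_range <- function(block) {
  n <- length(block)
  if (n < 2L) stop("block must have length >= 2", call. = FALSE)
  if (anyNA(block) || any(!is.finite(block))) {
    stop("block contains non-finite values", call. = FALSE)
  }
  z <- cumsum(block - mean(block))
  r <- max(z) - min(z)
  s <- stats::sd(block)
  if (s == 0) {
    list(R = r, S = 0, rs = NA_real_, degenerate = TRUE)
  } else {
    list(R = r, S = s, rs = r / s, degenerate = FALSE)
  }
}

#' R/S curve of a series
#'
#' For each window size `n` the series is segmented into `d = floor(l/n)`
#' blocks; `(R/S)_n` is the average of the per-block rescaled ranges over
#' the non-degenerate blocks. A window whose blocks are all degenerate is
#' skipped with a warning.
#'
#' @param x Numeric vector (length at least twice the smallest window).
#' @param config An [rs_config()].
#' @return Data frame of class `rs_statistics` with columns `n`, `d`
#'   (blocks formed), `d_used` (non-degenerate blocks) and `rs`.
#' @export
#' @examples
#' rs_curve(rep(c(1, 2, 3, 4), 4), rs_config(window_sizes = 8))
rs_curve <- function(x, config = rs_config()) {
  stopifnot(inherits(config, "rs_config"))
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("series contains non-finite values", call. = FALSE)
  }
  windows <- config$window_sizes
  if (is.null(windows)) windows <- dyadic_windows(length(x))
  if (max(windows) > length(x) %/% 2L) {
    windows <- windows[windows <= length(x) %/% 2L]
  }
  if (length(windows) == 0L) {
    stop("series of length ", length(x), " admits no window", call. = FALSE)
  }
  rows <- lapply(windows, function(n) {
    blocks <- segment_series(x, n)
    rs_vals <- vapply(blocks, function(b) rescaled_range(b)$rs, numeric(1))
    usable <- !is.na(rs_vals)
    data.frame(n = n, d = length(blocks), d_used = sum(usable),
               rs = if (any(usable)) mean(rs_vals[usable]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$rs)) {
    warning("window(s) ", paste(out$n[is.na(out$rs)], collapse = ", "),
            " skipped: all blocks degenerate (constant)", call. = FALSE)
    out <- out[!is.na(out$rs), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("rs_statistics", "data.frame")
  out
}

#' Expected rescaled range of an i.i.d. Gaussian block
#'
#' Exact finite-sample expectation `E[(R/S)_n]` for independent Gaussian
#' data (Anis--Lloyd form with the `(n - 1/2)/n` small-sample front factor),
#' computed with log-gamma for numerical stability. Used by the
#' `"anis-lloyd"` regression correction in [estimate_hurst()].
#'
#' @param n Integer vector of block lengths (`>= 2`).
#' @return Numeric vector of expectations.
#' @export
expected_rescaled_range <- function(n) {
  vapply(as.integer(n), function(nn) {
    if (nn < 2L) stop("n must be >= 2", call. = FALSE)
    i <- seq_len(nn - 1L)
    front <- (nn - 0.5) / nn
    g <- exp(lgamma((nn - 1) / 2) - lgamma(nn / 2)) / sqrt(pi)
    front * g * sum(sqrt((nn - i) / i))
  }, numeric(1))
}

#' Estimate the Hurst exponent by R/S regression
#'
#' Fits the scaling law `(R/S)_n ~ c * n^H` by ordinary least squares on
#' natural-log coordinates. With `correction = "anis-lloyd"` (the
#' [rs_config()] default) the regression is on
#' `log (R/S)_n - log E[(R/S)_n]` and the slope is recentred at 0.5, which
#' corrects the finite-sample upward bias of the plain statistic; with
#' `"none"` the slope of `log (R/S)_n` on `log n` is returned as is.
#'
#' The estimate is never clipped: values outside (0, 1) are reported with
#' `out_of_range = TRUE` so the anomaly stays visible.
#'
#' @param x Numeric vector (a reaction-time series).
#' @param config An [rs_config()].
#' @return Object of class `hurst_estimate`: a list with `H`, `log_c`
#'   (intercept of the fitted plain-regression line), `r_squared` (of the
#'   fitted regression), `windows`, `n_windows`, `correction` and
#'   `out_of_range`.
#' @export
#' @examples
#' set.seed(1)
#' estimate_hurst(rnorm(1024))
estimate_hurst <- function(x, config = rs_config()) {
  stopifnot(inherits(config, "rs_config"))
  curve <- rs_curve(x, config)
  if (nrow(curve) < config$min_windows) {
    stop("only ", nrow(curve), " usable window(s); at least ",
         config$min_windows, " required for the regression", call. = FALSE)
  }
  ln_n <- log(curve$n)
  ln_rs <- log(curve$rs)
  fit_slope <- function(y) {
    xc <- ln_n - mean(ln_n)
    slope <- sum(xc * (y - mean(y))) / sum(xc^2)
    intercept <- mean(y) - slope * mean(ln_n)
    resid <- y - (intercept + slope * ln_n)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
    list(slope = slope, intercept = intercept, r2 = r2)
  }
  if (config$correction == "anis-lloyd") {
    y <- ln_rs - log(expected_rescaled_range(curve$n))
    fit <- fit_slope(y)
    h <- 0.5 + fit$slope
  } else {
    fit <- fit_slope(ln_rs)
    h <- fit$slope
  }
  plain <- fit_slope(ln_rs)
  out <- structure(
    list(H = h, log_c = plain$intercept, r_squared = fit$r2,
         windows = curve$n, n_windows = nrow(curve),
         correction = config$correction,
         out_of_range = (h <= 0 || h >= 1)),
    class = "hurst_estimate"
  )
  if (out$out_of_range) {
    warning(sprintf("Hurst estimate %.4f outside (0, 1)", h), call. = FALSE)
  }
  out
}

#' @export
print.hurst_estimate <- function(x, ...) {
  cat(sprintf("Hurst estimate: H = %.4f  (R^2 = %.4f, %d windows, %s)\n",
              x$H, x$r_squared, x$n_windows,
              if (x$correction == "anis-lloyd") "Anis-Lloyd corrected"
              else "plain R/S regression"))
  if (x$out_of_range) cat("  warning: estimate outside (0, 1)\n")
  invisible(x)
}

#' Per-participant Hurst table for a cohort
#'
#' Convenience wrapper: estimates H on each participant's concatenated
#' reaction-time sequence.
#'
#' @param cohort An [ntt_cohort()].
#' @param config An [rs_config()].
#' @return Data frame with columns `participant_id`, `H`, `r_squared`,
#'   `n_windows`. Participants whose series cannot support the regression
#'   get `NA` with a warning.
#' @export
hurst_table <- function(cohort, config = rs_config()) {
  stopifnot(inherits(cohort, "ntt_cohort"))
  rows <- lapply(cohort$sequences, function(s) {
    est <- tryCatch(estimate_hurst(reaction_times(s), config),
                    error = function(e) e)
    if (inherits(est, "error")) {
      warning("participant ", s$participant_id, ": ",
              conditionMessage(est), call. = FALSE)
      data.frame(participant_id = s$participant_id, H = NA_real_,
                 r_squared = NA_real_, n_windows = NA_integer_)
    } else {
      data.frame(participant_id = s$participant_id, H = est$H,
                 r_squared = est$r_squared, n_windows = est$n_windows)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
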