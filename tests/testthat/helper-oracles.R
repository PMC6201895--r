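# Independent oracles and fixture builders shared across the suite.
# The oracles are deliberately naive (plain loops, no shared code with the
# package internals) so they can arbitrate the production path.

# Straight-line re-implementation of the R/S pipeline: segmentation into
# d = floor(l/n) blocks, per-block mean, cumulative deviations, range,
# unbiased sd, per-window average, then OLS of log(R/S) on log n.
oracle_hurst <- function(x, windows) {
  rs_per_window <- numeric(0)
  used <- integer(0)
  for (n in windows) {
    d <- floor(length(x) / n)
    vals <- c()
    for (m in 0:(d - 1)) {
      block <- x[(m * n + 1):(m * n + n)]
      em <- sum(block) / n
      y <- block - em
      z <- numeric(n)
      acc <- 0
      for (i in 1:n) {
        acc <- acc + y[i]
        z[i] <- acc
      }
      r <- max(z) - min(z)
      s <- sqrt(sum((block - em)^2) / (n - 1))
      if (s > 0) vals <- c(vals, r / s)
    }
    if (length(vals) > 0) {
      rs_per_window <- c(rs_per_window, mean(vals))
      used <- c(used, n)
    }
  }
  fit <- stats::lm(log(rs_per_window) ~ log(used))
  list(H = unname(stats::coef(fit)[2]),
       rs = stats::setNames(rs_per_window, used))
}

# Brute-force convex hull membership: a point is inside (or on) the hull
# polygon iff it is on the same side of every directed edge.
oracle_in_hull <- function(p, hull, tol = 1e-9) {
  nh <- nrow(hull)
  for (i in seq_len(nh)) {
    a <- hull[i, ]
    b <- hull[if (i == nh) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (cr < -tol) return(FALSE)
  }
  TRUE
}

# Small valid event table / sequence / cohort builders. NoD below the
# design range triggers an informative warning by design; fixtures silence
# it explicitly.
make_events <- function(n, tasks = 2L, decision = "Y", correct = TRUE,
                        rt = 1000) {
  per <- ceiling(n / tasks)
  task_index <- rep(seq_len(tasks), each = per)[seq_len(n)]
  data.frame(
    task_index = task_index,
    event_index = stats::ave(task_index, task_index, FUN = seq_along),
    decision = rep_len(decision, n),
    correct = rep_len(correct, n),
    reaction_time_ms = rep_len(rt, n)
  )
}

make_sequence <- function(id, n = 10L, ...) {
  suppressWarnings(response_sequence(id, make_events(n, ...)))
}

make_small_cohort <- function(ids = c("A", "B"), n = 10L) {
  ntt_cohort(lapply(ids, make_sequence, n = n))
}

# Frozen count of triangle-inequality violations of the symmetrized TLD
# distance over the seeded 1000-triple experiment in
# test-cluster_statistics.R (deterministic given with_seed(99)).
TRIANGLE_VIOLATIONS_2D <- 226L

# Random symmetric positive definite matrix of dimension d.
random_spd <- function(d) {
  a <- matrix(stats::rnorm(d * d), d, d)
  crossprod(a) + diag(d) * 0.1
}
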