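# Synthetic cohorts with the statistical structure the pipeline measures:
# reaction-time series with a prescribed Hurst exponent (exact fGn), a
# prescribed number of decisions, and a prescribed error rate, organized
# into latent groups.

#' Exact fractional Gaussian noise
#'
#' Generates a zero-mean, unit-variance stationary Gaussian sequence whose
#' autocovariance is `gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) / 2`
#' by circulant embedding of the covariance (Davies--Harte synthesis). The
#' method is exact: the output has the fGn covariance in distribution, not
#' an aggregation approximation. For `H = 0.5` the sequence is i.i.d.
#' standard Gaussian in distribution.
#'
#' @param n Length, at least 16.
#' @param H Target Hurst exponent, strictly inside (0, 1).
#' @param seed Optional integer seed; when given, the draw is a pure
#'   function of `(n, H, seed)` and the caller's RNG state is untouched.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' x <- generate_fgn(1024, H = 0.8, seed = 1)
#' stats::cor(x[-1], x[-length(x)]) # near 2^(2H-1) - 1
generate_fgn <- function(n, H, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 16L) stop("n must be an integer >= 16", call. = FALSE)
  if (!is.numeric(H) || length(H) != 1L || H <= 0 || H >= 1) {
    stop("H must lie strictly inside (0, 1)", call. = FALSE)
  }
  draw <- function() {
    k <- 0:n
    g <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
    row <- c(g, g[n:2])                # circulant first row, length 2n
    lam <- Re(stats::fft(row))
    # exact embedding: eigenvalues are non-negative for fGn; clip only
    # strictly negligible negative round-off
    if (min(lam) < -1e-8 * max(lam)) {
      stop("circulant embedding produced negative eigenvalues", call. = FALSE)
    }
    lam[lam < 0] <- 0
    m <- 2L * n
    z <- stats::rnorm(m) + 1i * stats::rnorm(m)
    w <- stats::fft(sqrt(lam / m) * z)
    Re(w)[seq_len(n)]
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Specification of one latent participant group
#'
#' A group prescribes the three quantities the analysis pipeline measures:
#' the Hurst exponent of the reaction-time series, the number of decisions
#' (NoD), and the error rate of decisions (ERD), plus the reaction-time
#' scale used to realize the series.
#'
#' @param target_H Hurst exponent in (0, 1).
#' @param target_NoD Number of decisions per participant, in \[200, 800\].
#' @param nod_sd Standard deviation of the per-participant NoD around
#'   `target_NoD` (default 0: every member has exactly `target_NoD`
#'   decisions). A positive value draws NoD from a rounded normal clamped
#'   to \[200, 800\], giving the within-group workload variability real
#'   cohorts show (and non-singular cluster covariances downstream).
#' @param target_ERD Error rate in \[0, 1\]; correctness is i.i.d.
#'   Bernoulli(1 - target_ERD).
#' @param n_participants Positive integer.
#' @param rt_mean_ms Mean reaction time (ms). Default `NULL` fills the
#'   24-minute session: `1440000 / target_NoD`.
#' @param rt_sd_ms Reaction-time standard deviation (ms). Default `NULL`
#'   uses 25% of the mean.
#' @param decision_mix Probabilities for the symbols Y, N, I (default
#'   0.45 / 0.45 / 0.10).
#' @param label Optional group label (used as the latent truth in recovery
#'   experiments).
#' @return Object of class `group_spec`.
#' @export
group_spec <- function(target_H, target_NoD, target_ERD, n_participants,
                       nod_sd = 0,
                       rt_mean_ms = NULL, rt_sd_ms = NULL,
                       decision_mix = c(Y = 0.45, N = 0.45, I = 0.10),
                       label = NULL) {
  if (target_H <= 0 || target_H >= 1) stop("target_H must be in (0, 1)", call. = FALSE)
  target_NoD <- as.integer(target_NoD)
  if (is.na(target_NoD) || target_NoD < 200L || target_NoD > 800L) {
    stop("target_NoD must be an integer in [200, 800]", call. = FALSE)
  }
  if (target_ERD < 0 || target_ERD > 1) stop("target_ERD must be in [0, 1]", call. = FALSE)
  if (!is.numeric(nod_sd) || nod_sd < 0) stop("nod_sd must be non-negative", call. = FALSE)
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 1L) {
    stop("n_participants must be a positive integer", call. = FALSE)
  }
  if (is.null(rt_mean_ms)) rt_mean_ms <- 1440000 / target_NoD
  if (is.null(rt_sd_ms)) rt_sd_ms <- 0.25 * rt_mean_ms
  if (rt_mean_ms <= 0 || rt_sd_ms <= 0) {
    stop("rt_mean_ms and rt_sd_ms must be positive", call. = FALSE)
  }
  if (length(decision_mix) != 3L || any(decision_mix < 0) ||
      abs(sum(decision_mix) - 1) > 1e-8) {
    stop("decision_mix must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  names(decision_mix) <- c("Y", "N", "I")
  structure(list(target_H = target_H, target_NoD = target_NoD,
                 nod_sd = nod_sd,
                 target_ERD = target_ERD, n_participants = n_participants,
                 rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
                 decision_mix = decision_mix, label = label),
            class = "group_spec")
}

#' Specification of a synthetic cohort
#'
#' @param groups List of [group_spec()] objects (at least one participant in
#'   total).
#' @param seed Integer seed; the generated cohort is a pure function of the
#'   spec, including this seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, seed = 1L) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  ok <- vapply(groups, inherits, logical(1), what = "group_spec")
  if (!length(groups) || !all(ok)) {
    stop("groups must be a list of group_spec objects", call. = FALSE)
  }
  total <- sum(vapply(groups, `[[`, integer(1), "n_participants"))
  if (total < 1L) stop("cohort must contain at least one participant", call. = FALSE)
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default synthetic study conditions
#'
#' Four latent groups mirroring the reference study's 3-dim cluster
#' centroids (workload W, Hurst H, error rate E) with sizes 75/51/11/6
#' (sum 143, the retained-cohort size); NoD is chosen so that the fixed
#' normalization bounds \[200, 800\] map it onto the target W.
#'
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L) {
  # (W, H, E) group conditions; NoD = 200 + 600 * W, rounded
  cond <- data.frame(
    W = c(0.2714, 0.5789, 0.3980, 0.6590),
    H = c(0.6032, 0.6675, 0.6683, 0.6490),
    E = c(0.0510, 0.0680, 0.5880, 0.8619),
    n = c(75L, 51L, 11L, 6L)
  )
  groups <- lapply(seq_len(nrow(cond)), function(i) {
    group_spec(target_H = cond$H[i],
               target_NoD = round(200 + 600 * cond$W[i]),
               nod_sd = 30,
               target_ERD = cond$E[i],
               n_participants = cond$n[i],
               label = paste0("G", i))
  })
  cohort_spec(groups, seed = seed)
}

#' Generate one synthetic participant
#'
#' Reaction times are an affine transform of exact fGn,
#' `rt_mean_ms + rt_sd_ms * fGn(target_H)`, truncated below at 50 ms so
#' every reaction time is positive; the truncation perturbs the realized
#' Hurst exponent only slightly at the default scales. The events are split
#' evenly into 2 session tasks. Correctness is i.i.d.
#' Bernoulli(1 - target_ERD); decision symbols are i.i.d. from the group's
#' Y/N/I mix.
#'
#' @param spec A [group_spec()].
#' @param id Participant id.
#' @param seed Integer seed for this participant.
#' @return A [response_sequence()] of exactly `spec$target_NoD` events.
#' @export
generate_participant <- function(spec, id, seed) {
  stopifnot(inherits(spec, "group_spec"))
  aux <- withr::with_seed(as.integer(seed) + 1L, {
    nod <- if (spec$nod_sd > 0) {
      max(200L, min(800L,
                    as.integer(round(stats::rnorm(1, spec$target_NoD,
                                                  spec$nod_sd)))))
    } else {
      spec$target_NoD
    }
    list(nod = nod,
         correct = stats::runif(nod) > spec$target_ERD,
         decision = sample(c("Y", "N", "I"), nod, replace = TRUE,
                           prob = spec$decision_mix))
  })
  nod <- aux$nod
  rt <- spec$rt_mean_ms +
    spec$rt_sd_ms * generate_fgn(nod, spec$target_H, seed = seed)
  rt <- pmax(rt, 50)
  n1 <- nod %/% 2L
  events <- data.frame(
    task_index = rep(c(1L, 2L), c(n1, nod - n1)),
    event_index = c(seq_len(n1), seq_len(nod - n1)),
    decision = aux$decision,
    correct = aux$correct,
    reaction_time_ms = rt
  )
  response_sequence(id, events)
}

#' Generate a synthetic cohort
#'
#' Deterministic given the spec: participant `i` of group `g` is drawn with
#' a seed derived from `spec$seed`, so the whole cohort is a pure function
#' of the spec. The latent group label of each participant is returned in
#' `provenance$group_labels` for recovery experiments.
#'
#' @param spec A [cohort_spec()].
#' @return An [ntt_cohort()] with `provenance$group_labels` (named character
#'   vector, one label per participant, cohort order).
#' @export
#' @examples
#' co <- generate_cohort(default_cohort_spec(seed = 7))
#' table(co$provenance$group_labels)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sequences <- list()
  labels <- character(0)
  counter <- 0L
  for (g in seq_along(spec$groups)) {
    gs <- spec$groups[[g]]
    lab <- if (is.null(gs$label)) paste0("G", g) else gs$label
    for (i in seq_len(gs$n_participants)) {
      counter <- counter + 1L
      id <- sprintf("P%03d", counter)
      # participant seeds spaced so the fGn draw and the aux draw never
      # collide across participants
      pseed <- (spec$seed * 100003L + counter * 2L) %% .Machine$integer.max
      sequences[[counter]] <- generate_participant(gs, id, seed = pseed)
      labels[counter] <- lab
    }
  }
  co <- ntt_cohort(sequences,
                   provenance = list(source = "synthetic",
                                     spec_seed = spec$seed,
                                     cleaning_log = character(0)))
  names(labels) <- participant_ids(co)
  co$provenance$group_labels <- labels
  co
}
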