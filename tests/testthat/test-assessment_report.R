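# The study's published 3-dim centroids; the factor-label and level rules
# are defined to reproduce the published qualitative grid from them.
study_centroids <- rbind(
  S1 = c(0.2714, 0.6032, 0.0510),
  S2 = c(0.5789, 0.6675, 0.0680),
  S3 = c(0.3980, 0.6683, 0.5880),
  S4 = c(0.6590, 0.6490, 0.8619)
)

test_that("factor labels rank span, stability and shift per cluster", {
  lab <- rank_factor_labels(study_centroids)
  expect_identical(lab$span, c("Bottom", "Moderate", "Low", "High"))
  expect_identical(lab$stability, c("Bottom", "Moderate", "High", "Low"))
  expect_identical(lab$distribution_shift,
                   c("High", "Moderate", "Low", "Bottom"))
  # each factor's labels are a permutation of the four names
  for (col in c("span", "stability", "distribution_shift")) {
    expect_setequal(lab[[col]], c("High", "Moderate", "Low", "Bottom"))
  }
})

test_that("factor labels are equivariant under cluster permutation and flag ties", {
  perm <- c(3, 1, 4, 2)
  lab <- rank_factor_labels(study_centroids)
  lab_p <- rank_factor_labels(study_centroids[perm, ])
  expect_identical(lab_p$span, lab$span[perm])
  expect_identical(lab_p$stability, lab$stability[perm])
  expect_identical(lab_p$distribution_shift, lab$distribution_shift[perm])

  tied <- matrix(0.5, 4, 3)
  expect_warning(lab_t <- rank_factor_labels(tied), "tied")
  expect_identical(lab_t$span, c("High", "Moderate", "Low", "Bottom"))

  # K != 4: numeric ranks, no four-name mapping
  lab3 <- rank_factor_labels(study_centroids[1:3, ])
  expect_true(is.numeric(lab3$span))
})

test_that("levels are the rank-sum order with an error-rate tie-break", {
  lab <- rank_factor_labels(study_centroids)
  lev <- assign_levels(lab, study_centroids)
  expect_identical(sort(lev$score), c(6L, 7L, 8L, 9L))
  expect_identical(lev$cluster[lev$level == 1], "S2")  # best cluster
  expect_identical(sort(lev$level), 1:4)               # bijection onto 1..4
  expect_identical(lev$level_name[lev$level == 1], "Excellent")
  expect_identical(lev$level_name[lev$level == 4], "Unqualified")

  # relabeling invariance
  perm <- c(2, 4, 1, 3)
  lev_p <- assign_levels(rank_factor_labels(study_centroids[perm, ]),
                         study_centroids[perm, ])
  expect_identical(lev_p$level, lev$level[perm])

  # a cluster ranked High on all three factors is Level 1
  ctr <- rbind(c(0.9, 0.9, 0.01), c(0.5, 0.5, 0.5),
               c(0.3, 0.4, 0.7), c(0.1, 0.2, 0.9))
  lev_top <- assign_levels(rank_factor_labels(ctr), ctr)
  expect_identical(lev_top$level[1], 1L)
  expect_identical(lev_top$score[1], 3L)
})

test_that("expert-style bands map features to the three-band grid", {
  f <- data.frame(participant_id = c("a", "b", "c"),
                  W = c(0.1, 0.5, 0.9), H = c(0.2, 0.5, 0.8),
                  E = c(0.05, 0.5, 0.95))
  th <- list(W = c(1 / 3, 2 / 3), H = c(1 / 3, 2 / 3), E = c(1 / 3, 2 / 3))
  bands <- expert_threshold_labels(f, th)
  expect_identical(bands$span_band, c("Narrow", "Medium", "Wide"))
  expect_identical(bands$stability_band, c("Bad", "Medium", "Good"))
  # E is inverted: a high error rate is the bad band
  expect_identical(bands$shift_band,
                   c("Rapid & Exact", "Medium", "Slow & Inaccurate"))
  expect_error(expert_threshold_labels(f, list(W = c(0.9, 0.1),
                                               H = th$H, E = th$E)),
               "cut points")

  # tercile defaults split a uniform cohort roughly in thirds
  set.seed(10)
  fu <- data.frame(participant_id = sprintf("p%03d", 1:300),
                   W = runif(300), H = runif(300), E = runif(300))
  counts <- table(expert_threshold_labels(fu)$span_band) / 300
  expect_true(all(abs(counts - 1 / 3) < 0.05))
})

test_that("the end-to-end report is complete, consistent and reproducible", {
  co <- generate_cohort(default_cohort_spec(seed = 31))
  rep1 <- assess_cohort(co, dim = 3, k = 4, seed = 3, restarts = 20)
  expect_s3_class(rep1, "assessment_report")
  expect_identical(nrow(rep1$centroids), 4L)
  expect_identical(sort(unique(rep1$assignments$cluster)),
                   c("S1", "S2", "S3", "S4"))
  expect_identical(nrow(rep1$levels), 4L)
  expect_identical(sort(rep1$levels$level), 1:4)
  for (pc in rep1$statistics$per_cluster) {
    expect_true(is.finite(pc$itm_unnormalized))
    expect_true(is.finite(pc$itm_per_dimension))
  }

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep1, d1)
  rep2 <- assess_cohort(co, dim = 3, k = 4, seed = 3, restarts = 20)
  write_report(rep2, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_true(all(file.exists(file.path(d1, c("features.csv", "centroids.csv",
                                              "factor_labels.csv",
                                              "levels.csv")))))
  # both ITM conventions are present and labeled in the JSON
  js <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_true(all(c("itm_unnormalized", "itm_per_dimension") %in%
                    names(js$clusters$S1)))

  # 2-dim run carries hulls instead of level tables
  rep2d <- assess_cohort(co, dim = 2, k = 4, seed = 3, restarts = 20)
  expect_null(rep2d$levels)
  expect_true(all(vapply(rep2d$statistics$per_cluster,
                         function(pc) !is.null(pc$hull), logical(1))))
})

test_that("mismatched report inputs raise integrity errors", {
  co <- generate_cohort(cohort_spec(list(group_spec(0.6, 300, 0.1, 8),
                                         group_spec(0.6, 500, 0.3, 8)),
                                    seed = 2))
  f <- extract_features(co, dim = 3, bounds_mode = "fixed")
  p <- kmeans_partition(f, k = 2, seed = 1, restarts = 5)
  st <- cluster_statistics(f, p)
  expect_error(build_report(f[1:10, ], p, st), "integrity")
  p2 <- kmeans_partition(f, k = 3, seed = 1, restarts = 5)
  expect_error(build_report(f, p2, st), "integrity")
})
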