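test_that("MAE matches hand arithmetic and rejects bad input", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(0, 10), c(10, 0)), 10)
  expect_equal(mae(c(7, 8, 9), c(8, 8, 8)), 2 / 3)
  expect_error(mae(1:3, 1:4), "length mismatch")
  expect_error(mae(numeric(0), numeric(0)), "empty")
  expect_error(mae(c(1, NA), c(1, 2)), "finite")
})

test_that("MAE is symmetric, shift-invariant, and zero iff equal", {
  set.seed(20)
  for (i in 1:20) {
    y <- rnorm(15); z <- rnorm(15); c0 <- rnorm(1)
    expect_equal(mae(y, z), mae(z, y))
    expect_equal(mae(y + c0, z + c0), mae(y, z), tolerance = 1e-12)
    expect_gt(mae(y, z), 0)
  }
})

test_that("grouped reports conserve counts and collapse correctly", {
  dat <- calibration_records(n_reviewers = 12L, per_reviewer = 20L, seed = 55L)
  rec <- dat$records
  ds <- build_designs(rec, formula_spec())
  fit <- estimate_lmm(ds)
  rec$calibrated_score <- calibrate_scores(fit, compute_blups(fit, ds), rec)$calibrated_score

  rep_dept <- grouped_report(rec, "department")
  expect_equal(sum(rep_dept$n_records[-1]), rep_dept$n_records[1])

  # a constant grouping key reproduces the overall row
  rec$one <- "all"
  rep_one <- grouped_report(rec, "one")
  expect_equal(rep_one$raw_mae[2], rep_one$raw_mae[1])
  expect_equal(rep_one$expert_mean[2], rep_one$expert_mean[1])

  # weighted-mean identity for per-record pooling
  rp <- grouped_report(rec, "department", pooled = TRUE)
  pooled_overall <- sum(rp$n_records[-1] * rp$raw_mae[-1]) / rp$n_records[1]
  expect_equal(pooled_overall, rp$raw_mae[1], tolerance = 1e-12)

  expect_error(grouped_report(rec, "no_such_column"), "unknown grouping key")
})

test_that("the paired signed-rank comparison has its exact small-sample law", {
  expect_equal(paired_comparison(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_true(paired_comparison(c(1, 2, 3), c(1, 2, 3))$degenerate)

  raw <- c(2, 3, 4, 5, 6, 7); cal <- c(1, 1, 2, 2, 3, 3)
  got <- paired_comparison(raw, cal, alternative = "greater")$p_value
  # oracle: enumerate all 2^6 sign assignments of the rank statistic
  d <- raw - cal
  r <- rank(abs(d))
  stats_all <- vapply(0:63, function(mask) {
    signs <- as.integer(intToBits(mask))[1:6]
    sum(r[signs == 1])
  }, numeric(1))
  p_enum <- mean(stats_all >= sum(r[d > 0]))
  expect_equal(got, p_enum)
  expect_equal(got, 1 / 64)

  # shift invariance of the statistic
  s1 <- paired_comparison(raw, cal, alternative = "greater")
  s2 <- paired_comparison(raw + 5, cal + 5, alternative = "greater")
  expect_equal(s1$statistic, s2$statistic)
  expect_equal(s1$p_value, s2$p_value)

  # sign-test option
  expect_equal(paired_comparison(raw, cal, "greater", method = "sign")$p_value,
               (1 / 2)^6)
  expect_error(paired_comparison(1, 1), "at least 2")
})

test_that("heatmaps aggregate cells correctly and keep empty cells missing", {
  one <- data.frame(reviewer_id = "r1", writer_id = "w1", department = "D1",
                    expert_score = 8.2, ai_score = 8.0)
  hm1 <- reviewer_writer_heatmap(one, "mean_score", "expert")
  expect_equal(dim(hm1$values), c(1L, 1L))
  expect_equal(hm1$values[1, 1], 8.2)

  dat <- calibration_records(n_reviewers = 10L, per_reviewer = 15L, seed = 66L)
  rec <- dat$records
  rec$calibrated_score <- rec$expert_score   # perfect predictions
  hm0 <- reviewer_writer_heatmap(rec, "mean_abs_error", "calibrated")
  expect_true(all(hm0$values[hm0$support > 0] == 0))
  expect_true(all(is.na(hm0$values[hm0$support == 0])))

  # a planted lenient reviewer shows up as a hot row
  sel <- rec$reviewer_id == "V003"
  rec$expert_score[sel] <- pmin(rec$expert_score[sel] + 1.5, 10)
  hm <- reviewer_writer_heatmap(rec, "mean_score", "expert")
  row_mean <- mean(hm$values["V003", ], na.rm = TRUE)
  expect_gt(row_mean, mean(hm$values, na.rm = TRUE))

  # support counts conserve records
  expect_equal(sum(hm$support), nrow(rec))
  tmp <- withr::local_tempfile()
  write_heatmap_tsv(hm, tmp)
  expect_true(file.exists(tmp) && file.exists(paste0(tmp, ".support")))
})

test_that("block summaries partition records and mirror the overall report", {
  dat <- calibration_records(n_reviewers = 8L, per_reviewer = 20L, seed = 44L)
  rec <- dat$records
  ds <- build_designs(rec, formula_spec())
  fit <- estimate_lmm(ds)
  rec$calibrated_score <- calibrate_scores(fit, compute_blups(fit, ds), rec)$calibrated_score

  all_one <- data.frame(entity_id = c(unique(rec$reviewer_id),
                                      unique(rec$writer_id)),
                        block = "A")
  bs <- block_summary(rec, all_one)
  ov <- grouped_report(rec, "overall")
  expect_equal(bs$raw_mae[1], ov$raw_mae[1])
  expect_equal(bs$n_records[1], ov$n_records[1])

  # disjoint reviewer/writer halves: counts sum to the covered subset
  revs <- sort(unique(rec$reviewer_id)); wrts <- sort(unique(rec$writer_id))
  two <- data.frame(entity_id = c(revs, wrts),
                    block = c(rep(c("A", "B"), length.out = length(revs)),
                              rep(c("A", "B"), length.out = length(wrts))))
  bs2 <- block_summary(rec, two)
  lookup <- setNames(two$block, two$entity_id)
  covered <- sum(lookup[rec$reviewer_id] == lookup[rec$writer_id])
  expect_equal(sum(bs2$n_records), covered)

  bad <- data.frame(entity_id = "V001", block = "Z")
  expect_error(block_summary(rec, bad), "no records")
})

test_that("quartile grouping ranks reviewers with stable ties", {
  base <- data.frame(
    reviewer_id = rep(c("r1", "r2", "r3", "r4"), each = 2),
    expert_score = rep(c(7, 7, 7, 7), each = 2),
    ai_score = 7,
    calibrated_score = rep(7 + c(1, 2, 3, 4) / 2, each = 2))
  qg <- quartile_grouping(base)
  expect_equal(qg$assignments$quartile, c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(qg$assignments$reviewer_id[qg$assignments$quartile == "Q1"], "r1")

  # all-equal MAEs: deterministic tie-break by reviewer id, sizes within 1
  tied <- base; tied$calibrated_score <- 7.5
  qt <- quartile_grouping(tied)
  expect_equal(sort(qt$assignments$quartile), c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(qt$assignments$quartile[order(qt$assignments$reviewer_id)],
               c("Q1", "Q2", "Q3", "Q4"))

  expect_error(quartile_grouping(base[base$reviewer_id != "r4", ]), "at least 4")
})

test_that("quartile assignment is permutation-equivariant", {
  set.seed(9)
  n <- 9L
  rec <- data.frame(reviewer_id = rep(sprintf("r%02d", 1:n), each = 3),
                    expert_score = rnorm(3 * n, 7),
                    ai_score = rnorm(3 * n, 7))
  rec$calibrated_score <- rec$expert_score + rnorm(3 * n, 0, 0.5)
  qg1 <- quartile_grouping(rec)
  perm <- sample(nrow(rec))
  qg2 <- quartile_grouping(rec[perm, ])
  m1 <- setNames(qg1$assignments$quartile, qg1$assignments$reviewer_id)
  m2 <- setNames(qg2$assignments$quartile, qg2$assignments$reviewer_id)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})
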