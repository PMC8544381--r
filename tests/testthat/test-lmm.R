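test_that("design matrices have the documented structure", {
  df <- data.frame(record_id = c("a", "b", "c", "d"),
                   reviewer_id = c("r1", "r1", "r2", "r2"),
                   expert_score = c(7, 8, 6, 7),
                   ai_score = c(7.1, 7.9, 6.2, 7.0),
                   department = "D1")
  ds <- build_designs(df, formula_spec())
  expect_length(ds, 2L)
  # single-level department contributes no indicator columns
  expect_identical(attr(ds, "fixed_cols"), c("(Intercept)", "ai_score"))
  expect_equal(ds[["r1"]]$Z, cbind(`(Intercept)` = c(1, 1)))
  expect_equal(ds[["r1"]]$X[, 1], c(1, 1))

  # 5 departments, random slope: q and p match the spec'd column counts
  set.seed(1)
  df5 <- data.frame(record_id = sprintf("x%02d", 1:40),
                    reviewer_id = rep(sprintf("r%d", 1:4), 10),
                    expert_score = rnorm(40, 7),
                    ai_score = rnorm(40, 7),
                    department = rep(sprintf("D%d", 1:5), 8))
  ds5 <- build_designs(df5, formula_spec(random = c("intercept", "ai_score")))
  expect_length(attr(ds5, "fixed_cols"), 1L + 1L + 4L)   # intercept + slope + 4 dummies
  expect_length(attr(ds5, "random_cols"), 2L)
  expect_warning(build_designs(transform(df5, ai_score = 1), formula_spec()),
                 "constant")
})

test_that("REML matches the ANOVA closed form on a balanced one-way design", {
  set.seed(3)
  m <- 20L; k <- 10L
  u <- rnorm(m, 0, 1)
  df <- data.frame(reviewer_id = rep(sprintf("V%02d", 1:m), each = k),
                   expert_score = 5 + rep(u, each = k) + rnorm(m * k, 0, 1),
                   record_id = sprintf("r%03d", seq_len(m * k)))
  ds <- build_designs(df, formula_spec(fixed = character(0)))
  fit <- estimate_lmm(ds)
  gm <- tapply(df$expert_score, df$reviewer_id, mean)
  MSW <- sum((df$expert_score - gm[df$reviewer_id])^2) / (m * (k - 1))
  MSB <- k * sum((gm - mean(df$expert_score))^2) / (m - 1)
  expect_equal(fit$sigma2, MSW, tolerance = 1e-6)
  expect_equal(fit$G[1, 1], (MSB - MSW) / k, tolerance = 1e-6)
})

test_that("REML agrees with lme4 on an unbalanced two-column design", {
  skip_if_not_installed("lme4")
  set.seed(8)
  n <- 400L
  rev <- sample(sprintf("V%02d", 1:25), n, TRUE)
  u <- rnorm(25, 0, 0.7)
  ai <- rnorm(n, 7, 1)
  df <- data.frame(reviewer_id = rev, ai_score = ai,
                   expert_score = 1 + 0.8 * ai + u[match(rev, sprintf("V%02d", 1:25))] +
                     rnorm(n, 0, 0.6),
                   record_id = sprintf("r%04d", 1:n))
  fit <- estimate_lmm(build_designs(df, formula_spec(fixed = "ai_score")))
  lf <- lme4::lmer(expert_score ~ ai_score + (1 | reviewer_id), df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$G[1, 1], vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(fit$B), unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
})

test_that("a null reviewer effect is estimated as (near) zero", {
  set.seed(5)
  n <- 5000L
  df <- data.frame(reviewer_id = rep(sprintf("V%02d", 1:50), each = 100),
                   expert_score = rnorm(n, 7, 1),
                   record_id = sprintf("r%05d", 1:n))
  fit <- estimate_lmm(build_designs(df, formula_spec(fixed = character(0))))
  expect_lte(fit$G[1, 1], 0.01)
})

test_that("the restricted likelihood at the optimum dominates the truth", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    m <- 12L; k <- 8L
    tau <- runif(1, 0.3, 1); sig <- runif(1, 0.3, 1)
    u <- rnorm(m, 0, tau)
    df <- data.frame(reviewer_id = rep(sprintf("V%02d", 1:m), each = k),
                     expert_score = 6 + rep(u, each = k) + rnorm(m * k, 0, sig),
                     record_id = seq_len(m * k))
    ds <- build_designs(df, formula_spec(fixed = character(0)))
    fit <- estimate_lmm(ds)
    nll_opt <- notescore:::neg_reml(fit$theta, ds, p = 1, q = 1)
    nll_truth <- notescore:::neg_reml(c(log(tau), log(sig)), ds, p = 1, q = 1)
    expect_lte(nll_opt, nll_truth + 1e-8)
  }
})

test_that("hand-solvable BLUP cases come out exactly", {
  fit1 <- list(B = c(`(Intercept)` = 0), G = matrix(1, 1, 1), sigma2 = 1,
               random_cols = "(Intercept)")
  d1 <- list(cluster_id = "c", Y = 2,
             X = matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)")),
             Z = matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(compute_blup(fit1, d1)$blup), 1.0)

  # G = 0: BLUP vanishes and B_m = B
  fit0 <- list(B = c(`(Intercept)` = 5), G = matrix(0, 1, 1), sigma2 = 1,
               random_cols = "(Intercept)")
  d4 <- list(cluster_id = "c", Y = c(9, 9, 9),
             X = matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)")),
             Z = matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)")))
  b0 <- compute_blup(fit0, d4)
  expect_equal(unname(b0$blup), 0)
  expect_equal(b0$B_m, fit0$B)
})

test_that("intercept-only BLUPs equal the closed-form shrinkage everywhere", {
  for (n in c(1L, 2L, 4L, 9L, 25L)) for (tau2 in c(0.25, 1, 4))
    for (s2 in c(0.5, 1, 2)) for (rbar in c(-1.5, 0.3, 1)) {
      fit <- list(B = c(`(Intercept)` = 0), G = matrix(tau2, 1, 1), sigma2 = s2,
                  random_cols = "(Intercept)")
      d <- list(cluster_id = "x", Y = rep(rbar, n),
                X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                Z = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
      expect_equal(unname(compute_blup(fit, d)$blup),
                   n * rbar * tau2 / (s2 + n * tau2), tolerance = 1e-10)
    }
})

test_that("BLUPs agree with Henderson's mixed-model equations", {
  for (seed in 1:30) {
    inst <- random_instance(seed)
    B <- gls_B(inst$designs, inst$G, inst$s2)
    fit <- list(B = setNames(B, colnames(inst$designs[[1]]$X)),
                G = inst$G, sigma2 = inst$s2,
                random_cols = colnames(inst$designs[[1]]$Z))
    mme <- henderson_blups(inst$designs, inst$G, inst$s2)
    expect_equal(unname(B), unname(mme$B), tolerance = 1e-8)
    for (j in seq_along(inst$designs)) {
      bl <- compute_blup(fit, inst$designs[[j]])
      expect_equal(unname(bl$blup), unname(mme$u[, j]), tolerance = 1e-8)
    }
  }
})

test_that("shrinkage is monotone in cluster size and variance ratio", {
  blup_of <- function(n, tau2, s2, rbar) {
    fit <- list(B = c(`(Intercept)` = 0), G = matrix(tau2, 1, 1), sigma2 = s2,
                random_cols = "(Intercept)")
    d <- list(cluster_id = "x", Y = rep(rbar, n),
              X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
              Z = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
    unname(compute_blup(fit, d)$blup)
  }
  vals <- vapply(1:20, blup_of, numeric(1), tau2 = 1, s2 = 1, rbar = 1)
  expect_true(all(diff(vals) >= 0))
  expect_equal(blup_of(5, 1e8, 1, 1.3), 1.3, tolerance = 1e-6)
  expect_equal(blup_of(5, 1e-12, 1, 1.3), 0, tolerance = 1e-6)
})

test_that("intercept BLUPs are centered on balanced designs", {
  set.seed(17)
  m <- 15L; k <- 6L
  df <- data.frame(reviewer_id = rep(sprintf("V%02d", 1:m), each = k),
                   expert_score = 7 + rep(rnorm(m, 0, 0.8), each = k) +
                     rnorm(m * k, 0, 0.5),
                   record_id = seq_len(m * k))
  ds <- build_designs(df, formula_spec(fixed = character(0)))
  fit <- estimate_lmm(ds)
  blups <- compute_blups(fit, ds)
  expect_lt(abs(mean(vapply(blups, function(b) b$blup[1], numeric(1)))), 1e-6)
})

test_that("calibration reduces a lenient reviewer's MAE and matches matrix arithmetic", {
  dat <- calibration_records(n_reviewers = 20L, per_reviewer = 30L, seed = 31L)
  rec <- dat$records
  # plant a strongly lenient reviewer on top of the generated effects
  lenient <- "V001"
  sel <- rec$reviewer_id == lenient
  rec$expert_score[sel] <- pmin(rec$expert_score[sel] + 1, 10)
  ds <- build_designs(rec, formula_spec())
  fit <- estimate_lmm(ds)
  blups <- compute_blups(fit, ds)
  cal <- calibrate_scores(fit, blups, rec)
  raw_mae <- mae(rec$expert_score[sel], rec$ai_score[sel])
  cal_mae <- mae(rec$expert_score[sel], cal$calibrated_score[sel])
  expect_lt(cal_mae, raw_mae)
  # independent matrix-product check, cluster by cluster
  for (m in names(ds)[1:5]) {
    idx <- match(ds[[m]]$record_id, cal$record_id)
    direct <- drop(ds[[m]]$X %*% fit$B + ds[[m]]$Z %*% blups[[m]]$blup)
    expect_equal(cal$calibrated_score[idx], direct, tolerance = 1e-10)
  }
  # unseen cluster falls back to the population prediction, flagged
  new_rec <- rec[1:2, ]; new_rec$reviewer_id <- "V999"
  cal_new <- calibrate_scores(fit, blups, new_rec)
  expect_true(all(cal_new$population_level))
  bx <- notescore:::build_X(new_rec, fit$spec$fixed, fit$levels)$X
  expect_equal(cal_new$calibrated_score,
               unname(drop(bx[, fit$fixed_cols] %*% fit$B)), tolerance = 1e-10)
})

test_that("a G = 0 fit calibrates to the population GLS prediction", {
  dat <- calibration_records(n_reviewers = 8L, per_reviewer = 10L, seed = 77L)
  rec <- dat$records
  ds <- build_designs(rec, formula_spec())
  fit <- estimate_lmm(ds)
  fit$G <- matrix(0, 1, 1, dimnames = dimnames(fit$G))
  blups <- compute_blups(fit, ds)
  cal <- calibrate_scores(fit, blups, rec)
  X <- notescore:::build_X(rec, fit$spec$fixed, fit$levels)$X
  expect_equal(cal$calibrated_score, unname(drop(X[, fit$fixed_cols] %*% fit$B)),
               tolerance = 1e-10)
})

test_that("missing covariates are filled by carry-forward or linear expectation", {
  h1 <- data.frame(ai_score = 6.5, dept = "D1")
  expect_equal(fill_covariates(h1, "carry_last"), h1, ignore_attr = TRUE)
  expect_error(fill_covariates(h1, "linear_expectation"), "at least 2")
  expect_error(fill_covariates(h1[0, ], "carry_last"), "at least 1")

  h3 <- data.frame(x = c(1, 2, 3))
  expect_equal(fill_covariates(h3, "linear_expectation")$x, 4.0, tolerance = 1e-10)

  hc <- data.frame(x = c(2, 2, 2), lab = c("a", "a", "a"))
  expect_equal(fill_covariates(hc, "carry_last")$x,
               fill_covariates(hc, "linear_expectation")$x, tolerance = 1e-10)
})
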