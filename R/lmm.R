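#' Specify the mixed-model design for score calibration
#'
#' Describes the columns of the fixed-effect design `X` (always led by an
#' intercept), the random-effect design `Z` (a subset of `X`'s columns), and
#' the clustering variable. The default — fixed effects intercept + raw AI
#' score + department indicators, random intercept per reviewer — is the
#' minimal design that lets a reviewer-specific leniency shift be estimated
#' on top of a population regression of expert scores on model scores.
#'
#' @param fixed character vector of record columns entering the fixed
#'   design; numeric columns enter as-is, character/factor columns are
#'   reference-coded (first level dropped; single-level factors contribute
#'   no columns).
#' @param random `"intercept"` or `c("intercept", "<numeric column>")` for a
#'   random slope; random columns must be a subset of the fixed columns.
#' @param cluster record column holding the cluster id (default reviewer).
#' @return An object of class `formula_spec`.
#' @export
formula_spec <- function(fixed = c("ai_score", "department"),
                         random = "intercept",
                         cluster = "reviewer_id") {
  if (!"intercept" %in% random)
    stopf("random effects must include \"intercept\"")
  extra <- setdiff(random, "intercept")
  if (length(extra) > 0L && !all(extra %in% fixed))
    stopf("random slope columns must be a subset of the fixed columns")
  structure(list(fixed = fixed, random = random, cluster = cluster),
            class = "formula_spec")
}

# Build the fixed-effect model matrix for a set of records, using stored
# factor levels when rebuilding at prediction time (unseen levels map to the
# reference with a warning).
build_X <- function(records, fixed, levels_map = NULL) {
  n <- nrow(records)
  cols <- list(`(Intercept)` = rep(1, n))
  lvls <- list()
  for (v in fixed) {
    if (!v %in% names(records)) stopf("record column `%s` not found", v)
    x <- records[[v]]
    if (is.numeric(x)) {
      if (any(!is.finite(x))) stopf("record column `%s` has non-finite values", v)
      cols[[v]] <- x
    } else {
      x <- as.character(x)
      lv <- if (!is.null(levels_map) && !is.null(levels_map[[v]]))
        levels_map[[v]] else sort(unique(x))
      lvls[[v]] <- lv
      unseen <- setdiff(unique(x), lv)
      if (length(unseen) > 0L) {
        warning(sprintf("column `%s`: unseen level(s) %s mapped to the reference level",
                        v, paste(unseen, collapse = ", ")), call. = FALSE)
        x[x %in% unseen] <- lv[1L]
      }
      if (length(lv) >= 2L)
        for (l in lv[-1L]) cols[[paste0(v, l)]] <- as.numeric(x == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, levels = lvls)
}

random_colnames <- function(spec) {
  c("(Intercept)", setdiff(spec$random, "intercept"))
}

#' Build per-cluster design matrices for the mixed model
#'
#' Splits the records into clusters (reviewers by default) and assembles,
#' for each cluster `m`, the response vector `Y_m` (expert scores), the
#' fixed design `X_m` (`n x q`, leading all-ones column) and the random
#' design `Z_m` (`n x p`, columns a subset of `X_m`'s).
#'
#' @param records data.frame with expert scores, AI scores and the cluster
#'   column; every fixed/random column referenced by `spec` must be present.
#' @param spec a [formula_spec()].
#' @param score_col column holding the response (default `"expert_score"`).
#' @return An object of class `cluster_designs`: a named list of per-cluster
#'   lists `(cluster_id, Y, X, Z, record_id)`, with the formula metadata
#'   (column names, factor levels) stored as attributes.
#' @export
build_designs <- function(records, spec = formula_spec(),
                          score_col = "expert_score") {
  stopifnot(inherits(spec, "formula_spec"), is.data.frame(records))
  if (!score_col %in% names(records)) stopf("missing response column `%s`", score_col)
  if (!spec$cluster %in% names(records))
    stopf("missing cluster column `%s`", spec$cluster)
  y <- records[[score_col]]
  if (any(!is.finite(y))) stopf("response contains non-finite values")
  bx <- build_X(records, spec$fixed, levels_map = NULL)
  X <- bx$X
  rand_cols <- random_colnames(spec)
  if (!all(rand_cols %in% colnames(X)))
    stopf("random columns (%s) must appear in the fixed design",
          paste(rand_cols, collapse = ", "))
  for (v in spec$fixed)
    if (is.numeric(records[[v]]) && length(unique(records[[v]])) == 1L)
      warning(sprintf("fixed column `%s` is constant; the design is rank-deficient",
                      v), call. = FALSE)
  cl <- as.character(records[[spec$cluster]])
  ids <- sort(unique(cl))
  designs <- lapply(ids, function(m) {
    rows <- which(cl == m)
    list(cluster_id = m,
         Y = y[rows],
         X = X[rows, , drop = FALSE],
         Z = X[rows, rand_cols, drop = FALSE],
         record_id = if ("record_id" %in% names(records))
           records$record_id[rows] else as.character(rows))
  })
  names(designs) <- ids
  structure(designs,
            class = "cluster_designs",
            fixed_cols = colnames(X),
            random_cols = rand_cols,
            spec = spec,
            levels = bx$levels,
            score_col = score_col)
}

#' @export
print.cluster_designs <- function(x, ...) {
  n <- sum(vapply(x, function(d) length(d$Y), numeric(1)))
  cat(sprintf("<cluster_designs> %d clusters, %d records; q = %d fixed, p = %d random columns\n",
              length(x), n, length(attr(x, "fixed_cols")),
              length(attr(x, "random_cols"))))
  invisible(x)
}

# log-Cholesky parameterization: theta = (log diag and strict lower triangle
# of L, column-major) with G = L L', followed by log(sigma). Guarantees G
# symmetric PSD and sigma^2 > 0 along the whole optimization path.
theta_to_G <- function(theta, p) {
  L <- matrix(0, p, p)
  k <- 1L
  for (j in seq_len(p)) for (i in j:p) {
    L[i, j] <- if (i == j) exp(theta[k]) else theta[k]
    k <- k + 1L
  }
  tcrossprod(L)
}

n_theta_G <- function(p) p * (p + 1L) / 2L

# Negative restricted log-likelihood (up to the additive constant handled by
# the caller). Uses per-cluster Cholesky solves; never inverts Sigma_m.
neg_reml <- function(theta, designs, p, q) {
  G <- theta_to_G(theta[seq_len(n_theta_G(p))], p)
  s2 <- exp(2 * theta[length(theta)])
  logdet <- 0
  XtSiX <- matrix(0, q, q); XtSiY <- numeric(q); YtSiY <- 0
  for (d in designs) {
    n <- length(d$Y)
    Sig <- d$Z %*% G %*% t(d$Z) + diag(s2, n)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- logdet + 2 * sum(log(diag(ch)))
    Xi <- backsolve(ch, d$X, transpose = TRUE)
    Yi <- backsolve(ch, d$Y, transpose = TRUE)
    XtSiX <- XtSiX + crossprod(Xi)
    XtSiY <- XtSiY + drop(crossprod(Xi, Yi))
    YtSiY <- YtSiY + sum(Yi^2)
  }
  chX <- tryCatch(chol(XtSiX), error = function(e) NULL)
  if (is.null(chX)) return(1e10)
  B <- backsolve(chX, backsolve(chX, XtSiY, transpose = TRUE))
  quad <- YtSiY - sum(XtSiY * B)
  val <- 0.5 * (logdet + 2 * sum(log(diag(chX))) + quad)
  if (!is.finite(val)) 1e10 else val
}

gls_fixed_effects <- function(designs, G, s2) {
  q <- length(attr(designs, "fixed_cols"))
  XtSiX <- matrix(0, q, q); XtSiY <- numeric(q)
  for (d in designs) {
    n <- length(d$Y)
    ch <- chol(d$Z %*% G %*% t(d$Z) + diag(s2, n))
    Xi <- backsolve(ch, d$X, transpose = TRUE)
    Yi <- backsolve(ch, d$Y, transpose = TRUE)
    XtSiX <- XtSiX + crossprod(Xi)
    XtSiY <- XtSiY + drop(crossprod(Xi, Yi))
  }
  list(B = setNames(solve(XtSiX, XtSiY), attr(designs, "fixed_cols")),
       XtSiX = XtSiX)
}

#' Estimate the linear mixed model by REML
#'
#' Fits `Y = XB + Zu + e` with `u ~ N(0, G)` per cluster and `e ~ N(0,
#' sigma^2 I)`: the random-effect covariance `G` and residual variance are
#' estimated by maximizing the restricted log-likelihood over a log-Cholesky
#' parameterization (quasi-Newton, [stats::nlminb()]), and the fixed-effect
#' vector `B` is the generalized-least-squares solution at the optimum.
#' REML (rather than ML) is used so variance components are not biased by
#' the estimated fixed effects.
#'
#' @param designs a [build_designs()] result with at least 2 clusters and
#'   more records than `q + p`.
#' @param max_iter optimizer iteration cap.
#' @param start optional starting value for `theta` (log-Cholesky of G,
#'   then log sigma).
#' @return An object of class `mixed_model_fit`: `B` (named q-vector), `G`
#'   (`p x p`), `sigma2`, `loglik` (restricted log-likelihood), `theta`,
#'   iteration count and convergence message, plus the design metadata
#'   needed to calibrate new records.
#' @export
estimate_lmm <- function(designs, max_iter = 500L, start = NULL) {
  stopifnot(inherits(designs, "cluster_designs"))
  if (length(designs) < 2L) stopf("need at least 2 clusters to estimate the LMM")
  q <- length(attr(designs, "fixed_cols"))
  p <- length(attr(designs, "random_cols"))
  n_tot <- sum(vapply(designs, function(d) length(d$Y), numeric(1)))
  if (n_tot <= q + p)
    stopf("too few records (%d) for q = %d fixed + p = %d random columns",
          n_tot, q, p)

  if (is.null(start)) {
    # moment starts: pooled OLS residual variance split between cluster-mean
    # spread and residual noise
    Y <- unlist(lapply(designs, `[[`, "Y"))
    X <- do.call(rbind, lapply(designs, `[[`, "X"))
    r <- tryCatch(stats::lsfit(X, Y, intercept = FALSE)$residuals,
                  error = function(e) Y - mean(Y))
    means <- vapply(designs, function(d) mean(d$Y), numeric(1))
    vb <- max(var(means) / 2, 1e-4)
    vw <- max(var(r) - vb, 1e-4)
    start <- c(0.5 * log(vb), rep(0, n_theta_G(p) - 1L), 0.5 * log(vw))
  }
  opt <- nlminb(start, neg_reml, designs = designs, p = p, q = q,
                control = list(iter.max = max_iter, eval.max = 4L * max_iter),
                lower = rep(-12, length(start)), upper = rep(12, length(start)))
  if (!opt$convergence %in% c(0L, 1L) ||
      grepl("iteration limit|max", tolower(opt$message)) && opt$iterations >= max_iter)
    stopf("REML did not converge after %d iterations: %s (objective %.6g)",
          opt$iterations, opt$message, opt$objective)
  G <- theta_to_G(opt$par[seq_len(n_theta_G(p))], p)
  s2 <- exp(2 * opt$par[length(opt$par)])
  dimnames(G) <- list(attr(designs, "random_cols"), attr(designs, "random_cols"))
  gls <- gls_fixed_effects(designs, G, s2)
  loglik <- -(opt$objective + 0.5 * (n_tot - q) * log(2 * pi))
  structure(list(B = gls$B, G = G, sigma2 = s2,
                 loglik = loglik, theta = opt$par,
                 iterations = opt$iterations, message = opt$message,
                 fixed_cols = attr(designs, "fixed_cols"),
                 random_cols = attr(designs, "random_cols"),
                 spec = attr(designs, "spec"),
                 levels = attr(designs, "levels"),
                 n_records = n_tot, n_clusters = length(designs)),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> REML, %d clusters / %d records\n",
              x$n_clusters, x$n_records))
  cat("  fixed effects B:\n")
  print(round(x$B, 4))
  cat("  random-effect covariance G:\n")
  print(round(x$G, 4))
  cat(sprintf("  sigma^2 = %.4f; restricted log-likelihood %.2f (%d iterations)\n",
              x$sigma2, x$loglik, x$iterations))
  invisible(x)
}

#' Best linear unbiased prediction for one cluster
#'
#' Computes the implied covariance of the cluster's responses,
#' \deqn{\Sigma_m = Z_m G Z_m^T + \sigma^2 I,}
#' then the BLUP of its random-effect vector,
#' \deqn{BLUP_m = G Z_m^T \Sigma_m^{-1} (Y_m - X_m B),}
#' and the cluster-specific coefficient vector `B_m = B + BLUP_m` (random
#' columns shifted by the BLUP; fixed-only columns carry `B` unchanged).
#' Linear systems are solved through the Cholesky factor of `Sigma_m`; the
#' matrix is never inverted explicitly, and a condition-number guard
#' rejects clusters whose `Sigma_m` is numerically singular.
#'
#' @param fit a [estimate_lmm()] result (or any list with `B`, `G`,
#'   `sigma2`, `random_cols`).
#' @param design one element of a [build_designs()] list.
#' @return An object of class `cluster_blup`: `cluster_id`, `blup`
#'   (named p-vector), `Sigma_m`, and `B_m` (named q-vector).
#' @export
compute_blup <- function(fit, design) {
  G <- fit$G; s2 <- fit$sigma2
  Z <- design$Z; X <- design$X; Y <- design$Y
  if (ncol(Z) != nrow(G)) stopf("Z has %d columns but G is %d x %d",
                                ncol(Z), nrow(G), ncol(G))
  n <- length(Y)
  Sig <- Z %*% G %*% t(Z) + diag(s2, n)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch))
    stopf("Sigma_m is not positive definite for cluster %s", design$cluster_id)
  dd <- diag(ch)
  if ((max(dd) / min(dd))^2 > 1e10)
    stopf("Sigma_m is numerically singular (condition > 1e10) for cluster %s",
          design$cluster_id)
  resid <- Y - drop(X %*% fit$B[colnames(X)])
  alpha <- backsolve(ch, backsolve(ch, resid, transpose = TRUE))
  blup <- drop(G %*% crossprod(Z, alpha))
  names(blup) <- colnames(Z)
  B_m <- fit$B
  B_m[names(blup)] <- B_m[names(blup)] + blup
  structure(list(cluster_id = design$cluster_id, blup = blup,
                 Sigma_m = Sig, B_m = B_m),
            class = "cluster_blup")
}

#' @rdname compute_blup
#' @param designs a full [build_designs()] list.
#' @return `compute_blups` returns a named list of `cluster_blup` objects.
#' @export
compute_blups <- function(fit, designs) {
  stopifnot(inherits(designs, "cluster_designs"))
  out <- lapply(designs, function(d) compute_blup(fit, d))
  names(out) <- names(designs)
  out
}

#' Calibrate raw model scores with cluster BLUPs
#'
#' Applies the fitted mixed model to records: the calibrated score of a
#' record is \eqn{x^T B + z^T BLUP_m} for its cluster `m` — the
#' cluster-specific regression `B_m = B + BLUP_m` evaluated at the record's
#' covariates. Records whose cluster was unseen at fit time receive the
#' population prediction (BLUP = 0) and are flagged.
#'
#' @param fit a [estimate_lmm()] result.
#' @param blups a [compute_blups()] result from the same fit.
#' @param records data.frame with the AI-score, cluster and fixed-effect
#'   columns used at fit time.
#' @return data.frame with `record_id`, `cluster_id`, `raw_ai_score`,
#'   `calibrated_score`, and logical `population_level`.
#' @export
calibrate_scores <- function(fit, blups, records) {
  stopifnot(inherits(fit, "mixed_model_fit"), is.data.frame(records))
  spec <- fit$spec
  ai_col <- setdiff(spec$random, "intercept")
  ai_col <- if (length(ai_col)) ai_col[1L] else "ai_score"
  if (!"ai_score" %in% names(records) || any(!is.finite(records$ai_score)))
    stopf("records must carry a finite `ai_score` column")
  X <- build_X(records, spec$fixed, levels_map = fit$levels)$X
  X <- X[, fit$fixed_cols, drop = FALSE]
  base <- drop(X %*% fit$B)
  Zrec <- X[, fit$random_cols, drop = FALSE]
  cl <- as.character(records[[spec$cluster]])
  bl_mat <- vapply(blups, `[[`, numeric(length(fit$random_cols)), "blup")
  bl_mat <- matrix(bl_mat, nrow = length(fit$random_cols),
                   dimnames = list(fit$random_cols, names(blups)))
  hit <- match(cl, colnames(bl_mat))
  shift <- numeric(nrow(records))
  seen <- !is.na(hit)
  if (any(seen))
    shift[seen] <- rowSums(Zrec[seen, , drop = FALSE] *
                             t(bl_mat[, hit[seen], drop = FALSE]))
  data.frame(record_id = if ("record_id" %in% names(records))
               records$record_id else as.character(seq_len(nrow(records))),
             cluster_id = cl,
             raw_ai_score = records$ai_score,
             calibrated_score = base + shift,
             population_level = !seen,
             stringsAsFactors = FALSE)
}

#' Fill in missing covariate rows from cluster history
#'
#' For forecasting at a time with unobserved covariates, completes the
#' covariate row from the cluster's history either by carrying the last
#' observed row forward (`carry_last`, needs one prior row) or by
#' per-covariate linear extrapolation against the observation index
#' (`linear_expectation`, needs two).
#'
#' @param history data.frame of prior covariate rows, in time order.
#' @param method `"carry_last"` or `"linear_expectation"`.
#' @param at index at which to predict (default: one past the history).
#' @return A one-row data.frame of completed covariates.
#' @export
fill_covariates <- function(history,
                            method = c("carry_last", "linear_expectation"),
                            at = nrow(history) + 1L) {
  method <- match.arg(method)
  stopifnot(is.data.frame(history))
  if (method == "carry_last") {
    if (nrow(history) < 1L)
      stopf("carry_last requires at least 1 prior observation")
    return(history[nrow(history), , drop = FALSE])
  }
  if (nrow(history) < 2L)
    stopf("linear_expectation requires at least 2 prior observations")
  out <- history[nrow(history), , drop = FALSE]
  idx <- seq_len(nrow(history))
  for (v in names(history)) {
    if (is.numeric(history[[v]])) {
      fitv <- lm(y ~ i, data = data.frame(y = history[[v]], i = idx))
      out[[v]] <- unname(predict(fitv, data.frame(i = at)))
    }
  }
  rownames(out) <- NULL
  out
}
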