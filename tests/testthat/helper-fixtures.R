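# Shared fixtures and independent oracles, all built in code at test time.

small_config <- function(...) {
  defaults <- list(n_records = 300L, n_writers = 12L, n_reviewers = 12L,
                   n_departments = 3L, vocab_size = 60L, doc_length = 30L,
                   n_marker_tokens = 6L, seed = 42L)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# Random embedding table over an artificial vocabulary.
random_table <- function(V = 30L, d = 5L, seed = 1L, prefix = "t") {
  set.seed(seed)
  embedding_table(sprintf("%s%03d", prefix, seq_len(V)),
                  matrix(rnorm(V * d), V, d))
}

random_orthogonal <- function(d, seed = 1L) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}

# Independent BLUP oracle: solve Henderson's mixed-model equations
#   [ X'X        X'Z_blk              ] [B]   [X'y]
#   [ Z_blk'X    Z_blk'Z_blk + s2*G^-1] [u] = [Z'y]
# jointly for the fixed effects and all cluster random effects.
henderson_blups <- function(designs, G, s2) {
  q <- ncol(designs[[1]]$X)
  p <- ncol(designs[[1]]$Z)
  m <- length(designs)
  X <- do.call(rbind, lapply(designs, `[[`, "X"))
  Y <- unlist(lapply(designs, `[[`, "Y"))
  n <- length(Y)
  Zblk <- matrix(0, n, p * m)
  row0 <- 0L
  for (j in seq_len(m)) {
    nj <- length(designs[[j]]$Y)
    Zblk[row0 + seq_len(nj), (j - 1L) * p + seq_len(p)] <- designs[[j]]$Z
    row0 <- row0 + nj
  }
  Ginv_blk <- kronecker(diag(m), solve(G))
  A <- rbind(cbind(crossprod(X), crossprod(X, Zblk)),
             cbind(crossprod(Zblk, X), crossprod(Zblk) + s2 * Ginv_blk))
  rhs <- c(crossprod(X, Y), crossprod(Zblk, Y))
  sol <- solve(A, rhs)
  list(B = sol[seq_len(q)],
       u = matrix(sol[-seq_len(q)], nrow = p))
}

# GLS fixed effects for given (G, s2) -- the B entering Eq.-style BLUPs.
gls_B <- function(designs, G, s2) {
  q <- ncol(designs[[1]]$X)
  XtSiX <- matrix(0, q, q); XtSiY <- numeric(q)
  for (d in designs) {
    Sig <- d$Z %*% G %*% t(d$Z) + diag(s2, length(d$Y))
    Si <- solve(Sig)
    XtSiX <- XtSiX + t(d$X) %*% Si %*% d$X
    XtSiY <- XtSiY + drop(t(d$X) %*% Si %*% d$Y)
  }
  solve(XtSiX, XtSiY)
}

# Random small mixed-model instance with SPD G, for oracle-equivalence runs.
random_instance <- function(seed) {
  set.seed(seed)
  m <- sample(2:5, 1)
  p <- sample(1:2, 1)
  q <- sample(p:3, 1)
  A <- matrix(rnorm(p * p), p, p)
  G <- crossprod(A) + diag(0.2, p)
  s2 <- runif(1, 0.3, 2)
  designs <- lapply(seq_len(m), function(j) {
    nj <- sample(max(2L, p):6L, 1)
    X <- cbind(1, matrix(rnorm(nj * (q - 1)), nj, q - 1))
    colnames(X) <- c("(Intercept)", if (q > 1) paste0("x", seq_len(q - 1)))
    list(cluster_id = paste0("c", j), Y = rnorm(nj, 5, 2),
         X = X, Z = X[, seq_len(p), drop = FALSE],
         record_id = paste0("r", j, "_", seq_len(nj)))
  })
  names(designs) <- vapply(designs, `[[`, character(1), "cluster_id")
  list(designs = designs, G = G, s2 = s2, m = m, p = p, q = q)
}

# Records + unbiased noisy AI scores for calibration tests.
calibration_records <- function(n_reviewers = 30L, per_reviewer = 40L,
                                tau = 0.6, ai_sd = 0.5, seed = 99L) {
  cfg <- generator_config(n_records = n_reviewers * per_reviewer,
                          n_reviewers = n_reviewers,
                          n_writers = 20L, n_departments = 4L,
                          reviewer_effect_sd = tau, residual_sd = 0.5,
                          vocab_size = 60L, doc_length = 10L, n_marker_tokens = 6L,
                          seed = seed)
  dat <- generate_scoring_dataset(cfg)
  dat$records <- simulate_ai_scores(dat$records, noise_sd = ai_sd,
                                    seed = seed + 1L)
  dat
}

per_reviewer_mae_vec <- function(records, col) {
  as.numeric(tapply(abs(records$expert_score - records[[col]]),
                    records$reviewer_id, mean))
}
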