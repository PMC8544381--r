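#' Embedding tables
#'
#' An embedding table maps an ordered vocabulary to rows of a `|vocab| x d`
#' real matrix. Tables are stored unnormalized; cosine comparisons normalize
#' on the fly.
#'
#' @param vocab character vector of distinct symbols.
#' @param vectors numeric matrix with one row per symbol.
#' @return An object of class `embedding_table`.
#' @export
embedding_table <- function(vocab, vectors) {
  vectors <- as.matrix(vectors)
  if (length(vocab) != nrow(vectors))
    stopf("vocab length (%d) != number of vector rows (%d)",
          length(vocab), nrow(vectors))
  if (anyDuplicated(vocab)) stopf("vocab contains duplicated symbols")
  if (any(!is.finite(vectors))) stopf("embedding vectors contain non-finite entries")
  if (ncol(vectors) < 2L) stopf("embedding dimension must be >= 2")
  rownames(vectors) <- vocab
  structure(list(vocab = as.character(vocab), vectors = vectors,
                 d = ncol(vectors)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d symbols x %d dims\n", length(x$vocab), x$d))
  invisible(x)
}

#' @export
dim.embedding_table <- function(x) dim(x$vectors)

tokenize_corpus <- function(corpus) {
  if (is.character(corpus)) strsplit(corpus, "[[:space:]]+") else corpus
}

# Symmetric windowed co-occurrence counts as a sparse V x V matrix.
cooccurrence_counts <- function(docs, vocab, window) {
  V <- length(vocab)
  M <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(V, V))
  for (off in seq_len(window)) {
    ii <- integer(0); jj <- integer(0)
    for (doc in docs) {
      n <- length(doc)
      if (n > off) {
        a <- match(doc[seq_len(n - off)], vocab)
        b <- match(doc[seq_len(n - off) + off], vocab)
        keep <- !is.na(a) & !is.na(b)
        ii <- c(ii, a[keep]); jj <- c(jj, b[keep])
      }
    }
    if (length(ii))
      M <- M + Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(V, V))
  }
  M + Matrix::t(M)
}

#' Train an embedding table from a corpus
#'
#' Deterministic, dependency-light trainer: windowed co-occurrence counts,
#' positive pointwise mutual information (PPMI) transform, then truncated
#' SVD, with rows \eqn{U_d \sqrt{S_d}}. The sign of each singular vector is
#' fixed so the largest-magnitude loading is positive, making the table
#' reproducible across runs. Tokens that never occur in the corpus are
#' absent from the table (no silent zero vectors).
#'
#' @param corpus character vector of whitespace-tokenized documents, or a
#'   list of token vectors.
#' @param d embedding dimension (must be < vocabulary size).
#' @param window symmetric co-occurrence window width.
#' @param seed unused by the deterministic SVD backend but kept in the
#'   signature so stochastic backends slot in unchanged.
#' @return An [embedding_table()].
#' @export
train_embeddings <- function(corpus, d = 16L, window = 5L, seed = 1L) {
  docs <- tokenize_corpus(corpus)
  docs <- docs[lengths(docs) > 0L]
  if (length(docs) == 0L) stopf("corpus is empty")
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  d <- check_count(d, "d", min = 2L)
  if (d >= length(vocab))
    stopf("embedding dimension d (%d) must be < vocabulary size (%d)",
          d, length(vocab))
  window <- check_count(window, "window")

  C <- cooccurrence_counts(docs, vocab, window)
  total <- sum(C)
  if (total == 0) stopf("no co-occurrences found (documents of length 1?)")
  rs <- Matrix::rowSums(C)
  # PMI_ij = log( c_ij * total / (r_i * r_j) ); keep positive part
  P <- as.matrix(C)
  denom <- outer(rs, rs)
  pos <- P > 0
  P[pos] <- log(P[pos] * total / denom[pos])
  P[P < 0] <- 0
  sv <- svd(P, nu = d, nv = 0)
  vec <- sv$u %*% diag(sqrt(sv$d[seq_len(d)]), d)
  # sign convention: dominant loading of each dimension positive
  for (j in seq_len(d)) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  embedding_table(vocab, vec)
}

#' Fit the linear projection between two embedding tables
#'
#' Solves \eqn{W = \arg\min_W \|S W - T\|_F} by ordinary least squares over
#' the rows of the shared vocabulary, where `S` holds source-table vectors
#' and `T` target-table vectors. The fitted `W` carries every source
#' coordinate into the target coordinate system by matrix multiplication;
#' applying it with [project_table()] preserves the full source vocabulary.
#' A ridge penalty (`lambda > 0`) is available for ill-conditioned shared
#' sets, and `method = "procrustes"` constrains `W` to be orthogonal.
#'
#' @param source,target [embedding_table()] objects sharing vocabulary.
#' @param lambda ridge penalty (default 0 = plain OLS).
#' @param method `"ols"` (default) or `"procrustes"` (orthogonal `W` via
#'   SVD of the cross-covariance).
#' @return An object of class `projection_matrix`: list with `W`
#'   (`d_source x d_target`), `fit_residual` (Frobenius norm of the training
#'   residual), `shared_vocab_used`, and `method`.
#' @export
fit_projection <- function(source, target, lambda = 0, method = c("ols", "procrustes")) {
  stopifnot(inherits(source, "embedding_table"), inherits(target, "embedding_table"))
  method <- match.arg(method)
  shared <- intersect(source$vocab, target$vocab)
  if (length(shared) < source$d)
    stopf("shared vocabulary (%d symbols) smaller than source dimension (%d)",
          length(shared), source$d)
  S <- source$vectors[shared, , drop = FALSE]
  Tm <- target$vectors[shared, , drop = FALSE]
  if (method == "procrustes") {
    if (source$d != target$d)
      stopf("procrustes projection requires equal source/target dimensions")
    sv <- svd(crossprod(S, Tm))
    W <- sv$u %*% t(sv$v)
  } else {
    StS <- crossprod(S)
    if (lambda > 0) StS <- StS + diag(lambda, source$d)
    r <- qr(StS)
    if (r$rank < source$d)
      stopf(paste0("source rows over the shared vocabulary are rank-deficient ",
                   "(rank %d < d_source %d); supply lambda > 0 or more shared symbols"),
            r$rank, source$d)
    W <- solve(r, crossprod(S, Tm))
  }
  dimnames(W) <- NULL
  resid <- S %*% W - Tm
  structure(list(W = W,
                 fit_residual = sqrt(sum(resid^2)),
                 shared_vocab_used = shared,
                 method = method,
                 lambda = lambda),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("<projection_matrix> %d x %d (%s), fit residual %.4g over %d shared symbols\n",
              nrow(x$W), ncol(x$W), x$method, x$fit_residual,
              length(x$shared_vocab_used)))
  invisible(x)
}

#' Project an embedding table into a new coordinate system
#'
#' Multiplies every source vector by the projection matrix. The full source
#' vocabulary survives: symbols absent from the target table used to fit
#' the projection are still carried into the target coordinate system,
#' which is the point of projection embeddings — open-corpus vocabulary
#' diversity is retained inside the domain geometry.
#'
#' @param source an [embedding_table()].
#' @param projection a `projection_matrix` from [fit_projection()], or a
#'   bare `d_source x d_target` matrix.
#' @return An [embedding_table()] over the same vocabulary.
#' @export
project_table <- function(source, projection) {
  stopifnot(inherits(source, "embedding_table"))
  W <- if (inherits(projection, "projection_matrix")) projection$W else as.matrix(projection)
  if (nrow(W) != source$d)
    stopf("projection expects %d source dimensions, table has %d", nrow(W), source$d)
  embedding_table(source$vocab, source$vectors %*% W)
}

#' Concatenate embedding tables column-wise
#'
#' Restricts all tables to their common vocabulary (in the first table's
#' order) and binds the vector blocks side by side, so a downstream model
#' can refer to several embedding sources simultaneously.
#'
#' @param tables list of [embedding_table()] objects.
#' @return An [embedding_table()] with `d = sum(d_i)`.
#' @export
concat_embeddings <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "embedding_table")))
  vocab <- Reduce(intersect, lapply(tables, `[[`, "vocab"))
  vocab <- tables[[1L]]$vocab[tables[[1L]]$vocab %in% vocab]
  if (length(vocab) == 0L) stopf("tables share no vocabulary")
  blocks <- lapply(tables, function(tb) tb$vectors[vocab, , drop = FALSE])
  embedding_table(vocab, do.call(cbind, blocks))
}

#' Cosine similarity between the rows of two embedding tables
#'
#' @param a,b [embedding_table()] objects.
#' @param symbols symbols to compare (default: shared vocabulary).
#' @return named numeric vector of cosines.
#' @export
embedding_cosines <- function(a, b, symbols = NULL) {
  if (is.null(symbols)) symbols <- intersect(a$vocab, b$vocab)
  va <- a$vectors[symbols, , drop = FALSE]
  vb <- b$vectors[symbols, , drop = FALSE]
  num <- rowSums(va * vb)
  den <- sqrt(rowSums(va^2)) * sqrt(rowSums(vb^2))
  setNames(ifelse(den > 0, num / den, NA_real_), symbols)
}

#' Read and write embedding tables in word2vec text format
#'
#' Header line `"N d"`, then one `"token v1 ... vd"` line per symbol.
#' Projection matrices are written as TSV with a one-line JSON header
#' carrying shapes and the fit residual.
#'
#' @param table an [embedding_table()]; `proj` a `projection_matrix`.
#' @param path file path.
#' @name embedding_io
NULL

#' @rdname embedding_io
#' @export
write_word2vec <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(table$vocab), table$d), con)
  body <- vapply(seq_along(table$vocab), function(i)
    paste(table$vocab[i],
          paste(sprintf("%.17g", table$vectors[i, ]), collapse = " ")),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname embedding_io
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  parts <- strsplit(trimws(lines[-1L]), "[[:space:]]+")
  vocab <- vapply(parts, `[[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[2L])))
  if (length(vocab) != hdr[1L]) stopf("word2vec header count mismatch in %s", path)
  embedding_table(vocab, vec)
}

#' @rdname embedding_io
#' @param proj a `projection_matrix`.
#' @export
write_projection <- function(proj, path) {
  stopifnot(inherits(proj, "projection_matrix"))
  hdr <- jsonlite::toJSON(list(d_source = nrow(proj$W), d_target = ncol(proj$W),
                               fit_residual = proj$fit_residual,
                               method = proj$method, lambda = proj$lambda,
                               n_shared = length(proj$shared_vocab_used)),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.table(proj$W, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname embedding_io
#' @export
read_projection <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1L]))
  W <- do.call(rbind, lapply(strsplit(lines[-1L], "\t", fixed = TRUE), as.numeric))
  structure(list(W = W, fit_residual = meta$fit_residual,
                 shared_vocab_used = character(0),
                 method = meta$method, lambda = meta$lambda),
            class = "projection_matrix")
}
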