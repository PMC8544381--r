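#' Configuration for the synthetic scored-record generator
#'
#' Bundles every knob of the simulated review study: corpus sizes, the latent
#' quality model, rater (reviewer) random effects, the token-emission model
#' linking record text to quality, and the RNG seed. The generative model is
#'
#' \deqn{q_{rec} = \mu_{dept} + w_{writer} + \epsilon_q,\qquad
#'       y_{rec} = q_{rec} + u_{rev} + s_{rev}(q_{rec} - \bar\mu) + e,}
#'
#' with \eqn{u_{rev} \sim N(0, \tau^2)} the reviewer leniency intercept,
#' \eqn{s_{rev} \sim N(0, \code{reviewer_slope_sd}^2)} an optional random
#' slope, and \eqn{e \sim N(0, \sigma^2)} residual rating noise. Scores are
#' clipped to \[score_min, score_max\] (a 10-point scale by default).
#'
#' @param n_departments,n_writers,n_reviewers,n_records positive counts.
#' @param quality_sd SD of record-level latent quality around the
#'   writer/department mean, in score units.
#' @param writer_sd SD of the persistent per-writer quality offset (score
#'   units); set 0 for department-mean-only latent quality.
#' @param reviewer_effect_sd SD \eqn{\tau} of the reviewer leniency random
#'   intercept, score units.
#' @param reviewer_slope_sd SD of the reviewer random slope on (centered)
#'   latent quality; default 0 (slopes off).
#' @param residual_sd residual rating noise SD \eqn{\sigma}, score units.
#' @param score_min,score_max score bounds (default 0 and 10).
#' @param vocab_size number of distinct token symbols; must be at least
#'   twice the total number of marker tokens.
#' @param doc_length tokens per generated record text.
#' @param n_marker_tokens marker tokens per tier. Two tiers exist: "quality
#'   markers" whose emission probability rises linearly in latent quality
#'   (these are the markers of the monotonicity contract) and "deficiency
#'   markers" whose probability falls.
#' @param marker_budget maximum total probability a tier can reach at full
#'   signal, unitless in (0, 1).
#' @param quality_signal_strength multiplier in \[0, 1\] on the marker
#'   emission probabilities; 0 makes text independent of quality.
#' @param dept_mean,dept_mean_sd department mean scores are drawn
#'   N(dept_mean, dept_mean_sd^2), mimicking the high-scoring regime of
#'   routine record review.
#' @param erratic_fraction fraction of reviewers that are "erratic" (extra
#'   rating noise); default 0.
#' @param erratic_extra_sd additional residual SD for erratic reviewers.
#' @param round_scores round expert scores to 0.1 (Likert-style reporting).
#' @param seed integer RNG seed; identical seeds give identical datasets.
#'
#' @return An object of class `generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(n_records = 200, seed = 1)
#' dat <- generate_scoring_dataset(cfg)
#' head(dat$records[, c("record_id", "reviewer_id", "expert_score")])
generator_config <- function(n_departments = 4L,
                             n_writers = 30L,
                             n_reviewers = 30L,
                             n_records = 2000L,
                             quality_sd = 1.0,
                             writer_sd = 0.5,
                             reviewer_effect_sd = 0.6,
                             reviewer_slope_sd = 0,
                             residual_sd = 0.5,
                             score_min = 0,
                             score_max = 10,
                             vocab_size = 200L,
                             doc_length = 100L,
                             n_marker_tokens = 12L,
                             marker_budget = 0.6,
                             quality_signal_strength = 0.8,
                             dept_mean = 7.5,
                             dept_mean_sd = 0.5,
                             erratic_fraction = 0,
                             erratic_extra_sd = 2,
                             round_scores = FALSE,
                             seed = 1L) {
  cfg <- list(
    n_departments = check_count(n_departments, "n_departments"),
    n_writers = check_count(n_writers, "n_writers"),
    n_reviewers = check_count(n_reviewers, "n_reviewers"),
    n_records = check_count(n_records, "n_records"),
    quality_sd = check_nonneg(quality_sd, "quality_sd"),
    writer_sd = check_nonneg(writer_sd, "writer_sd"),
    reviewer_effect_sd = check_nonneg(reviewer_effect_sd, "reviewer_effect_sd"),
    reviewer_slope_sd = check_nonneg(reviewer_slope_sd, "reviewer_slope_sd"),
    residual_sd = check_nonneg(residual_sd, "residual_sd"),
    score_min = as.numeric(score_min),
    score_max = as.numeric(score_max),
    vocab_size = check_count(vocab_size, "vocab_size", min = 2L),
    doc_length = check_count(doc_length, "doc_length"),
    n_marker_tokens = check_count(n_marker_tokens, "n_marker_tokens"),
    marker_budget = check_nonneg(marker_budget, "marker_budget"),
    quality_signal_strength = check_nonneg(quality_signal_strength,
                                           "quality_signal_strength"),
    dept_mean = as.numeric(dept_mean),
    dept_mean_sd = check_nonneg(dept_mean_sd, "dept_mean_sd"),
    erratic_fraction = check_nonneg(erratic_fraction, "erratic_fraction"),
    erratic_extra_sd = check_nonneg(erratic_extra_sd, "erratic_extra_sd"),
    round_scores = isTRUE(round_scores),
    seed = as.integer(seed)
  )
  if (cfg$score_min >= cfg$score_max)
    stopf("score_min (%g) must be < score_max (%g)", cfg$score_min, cfg$score_max)
  if (cfg$quality_signal_strength > 1)
    stopf("quality_signal_strength must lie in [0, 1]")
  if (cfg$marker_budget >= 1)
    stopf("marker_budget must be < 1")
  if (cfg$erratic_fraction > 1)
    stopf("erratic_fraction must lie in [0, 1]")
  if (cfg$vocab_size < 2L * (2L * cfg$n_marker_tokens))
    stopf("vocab_size (%d) must be >= twice the number of marker tokens (2 tiers x %d)",
          cfg$vocab_size, cfg$n_marker_tokens)
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  records: %d  (writers %d, reviewers %d, departments %d)\n",
              x$n_records, x$n_writers, x$n_reviewers, x$n_departments))
  cat(sprintf("  score range [%g, %g]; quality_sd %g, tau %g, sigma %g\n",
              x$score_min, x$score_max, x$quality_sd,
              x$reviewer_effect_sd, x$residual_sd))
  cat(sprintf("  vocab %d, doc_length %d, signal strength %g, seed %d\n",
              x$vocab_size, x$doc_length, x$quality_signal_strength, x$seed))
  invisible(x)
}

vocab_tokens <- function(cfg) sprintf("w%04d", seq_len(cfg$vocab_size))

# Token tiers: quality markers (emission prob rises with quality),
# deficiency markers (falls), Zipf background for the rest.
marker_tokens <- function(cfg) {
  v <- vocab_tokens(cfg)
  m <- cfg$n_marker_tokens
  list(quality = v[seq_len(m)],
       deficiency = v[m + seq_len(m)],
       background = v[-seq_len(2L * m)])
}

division_labels <- c("Internal medicine", "Surgery",
                     "Obstetrics and pediatrics", "Other departments")

#' Generate a reviewer-scored record corpus with known ground truth
#'
#' Simulates departments, writers, reviewers and scored records under the
#' model described in [generator_config()]. Returns both the observable data
#' (records with text and an expert score) and the truth table of latent
#' effects, so that downstream estimators (REML variance components, BLUPs,
#' quartile diagnostics) can be tested against the generating values.
#'
#' @param cfg a [generator_config()].
#' @return A list with components:
#'   \describe{
#'     \item{records}{data.frame with record_id, writer_id, reviewer_id,
#'       department, division, time (integer order index), text
#'       (whitespace-joined tokens), latent_quality and expert_score.}
#'     \item{truth}{list of data.frames: `departments` (mean score, division),
#'       `writers` (department, effect), `reviewers` (department, intercept,
#'       slope, erratic flag).}
#'   }
#' @export
generate_scoring_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    depts <- sprintf("D%02d", seq_len(cfg$n_departments))
    dept_mu <- clip(rnorm(cfg$n_departments, cfg$dept_mean, cfg$dept_mean_sd),
                    cfg$score_min, cfg$score_max)
    dept_div <- division_labels[(seq_len(cfg$n_departments) - 1L) %% 4L + 1L]

    writer_ids <- sprintf("W%03d", seq_len(cfg$n_writers))
    writer_dept <- depts[(seq_len(cfg$n_writers) - 1L) %% cfg$n_departments + 1L]
    writer_eff <- rnorm(cfg$n_writers, 0, cfg$writer_sd)

    reviewer_ids <- sprintf("V%03d", seq_len(cfg$n_reviewers))
    reviewer_dept <- depts[(seq_len(cfg$n_reviewers) - 1L) %% cfg$n_departments + 1L]
    reviewer_u <- rnorm(cfg$n_reviewers, 0, cfg$reviewer_effect_sd)
    reviewer_s <- rnorm(cfg$n_reviewers, 0, cfg$reviewer_slope_sd)
    n_err <- round(cfg$erratic_fraction * cfg$n_reviewers)
    erratic <- rep(FALSE, cfg$n_reviewers)
    if (n_err > 0) erratic[sample.int(cfg$n_reviewers, n_err)] <- TRUE

    n <- cfg$n_records
    # balanced-ish assignment: cycle writers, then cycle reviewers within the
    # record's department so per-reviewer workloads are near equal
    w_idx <- sample(rep_len(seq_len(cfg$n_writers), n))
    dept <- writer_dept[w_idx]
    r_idx <- integer(n)
    for (d in depts) {
      rows <- which(dept == d)
      cand <- which(reviewer_dept == d)
      if (length(cand) == 0L) cand <- seq_len(cfg$n_reviewers)
      r_idx[rows] <- sample(rep_len(cand, length(rows)))
    }

    latent <- clip(rnorm(n, dept_mu[match(dept, depts)] + writer_eff[w_idx],
                         cfg$quality_sd),
                   cfg$score_min, cfg$score_max)
    extra <- ifelse(erratic[r_idx], cfg$erratic_extra_sd, 0)
    e <- rnorm(n, 0, sqrt(cfg$residual_sd^2 + extra^2))
    score <- latent + reviewer_u[r_idx] +
      reviewer_s[r_idx] * (latent - cfg$dept_mean) + e
    score <- clip(score, cfg$score_min, cfg$score_max)
    if (cfg$round_scores) score <- round(score, 1)

    text <- generate_record_text(latent, cfg)

    records <- data.frame(
      record_id = sprintf("R%06d", seq_len(n)),
      writer_id = writer_ids[w_idx],
      reviewer_id = reviewer_ids[r_idx],
      department = dept,
      division = dept_div[match(dept, depts)],
      time = seq_len(n),
      text = text,
      latent_quality = latent,
      expert_score = score,
      stringsAsFactors = FALSE
    )
    truth <- list(
      departments = data.frame(department = depts, division = dept_div,
                               mu = dept_mu, stringsAsFactors = FALSE),
      writers = data.frame(writer_id = writer_ids, department = writer_dept,
                           effect = writer_eff, stringsAsFactors = FALSE),
      reviewers = data.frame(reviewer_id = reviewer_ids,
                             department = reviewer_dept,
                             intercept = reviewer_u, slope = reviewer_s,
                             erratic = erratic, stringsAsFactors = FALSE)
    )
    list(records = records, truth = truth)
  })
}

#' Generate token sequences whose composition encodes latent quality
#'
#' Each document has exactly `cfg$doc_length` tokens. At each position a
#' quality marker is emitted with probability
#' `quality_signal_strength * marker_budget * q_norm` and a deficiency marker
#' with probability `quality_signal_strength * marker_budget * (1 - q_norm)`,
#' where `q_norm` is latent quality rescaled to \[0, 1\]; otherwise a
#' background token is drawn from a Zipf distribution. Quality-marker
#' frequency is therefore monotone increasing in latent quality, with
#' strength 0 removing any text-quality association.
#'
#' @param latent_quality numeric vector of latent qualities within the score
#'   bounds; one document is generated per element.
#' @param cfg a [generator_config()].
#' @param seed optional seed; by default the current RNG stream is used (as
#'   when called from [generate_scoring_dataset()]).
#' @return character vector of whitespace-joined token sequences.
#' @export
generate_record_text <- function(latent_quality, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  s <- cfg$quality_signal_strength
  if (s < 0 || s > 1) stopf("quality_signal_strength must lie in [0, 1]")
  if (any(latent_quality < cfg$score_min - 1e-9) ||
      any(latent_quality > cfg$score_max + 1e-9))
    stopf("latent_quality outside [%g, %g]", cfg$score_min, cfg$score_max)
  with_seed(seed, {
    tiers <- marker_tokens(cfg)
    L <- cfg$doc_length
    n <- length(latent_quality)
    if (n == 0L) return(character(0))
    qn <- (latent_quality - cfg$score_min) / (cfg$score_max - cfg$score_min)
    p_hi <- rep(s * cfg$marker_budget * qn, each = L)
    p_lo <- rep(s * cfg$marker_budget * (1 - qn), each = L)
    u <- runif(n * L)
    kind <- ifelse(u < p_hi, 1L, ifelse(u < p_hi + p_lo, 2L, 3L))
    zipf <- 1 / seq_along(tiers$background)
    tok <- character(n * L)
    n1 <- sum(kind == 1L); n2 <- sum(kind == 2L); n3 <- sum(kind == 3L)
    if (n1) tok[kind == 1L] <- sample(tiers$quality, n1, replace = TRUE)
    if (n2) tok[kind == 2L] <- sample(tiers$deficiency, n2, replace = TRUE)
    if (n3) tok[kind == 3L] <- sample(tiers$background, n3, replace = TRUE,
                                      prob = zipf)
    docs <- matrix(tok, nrow = L)
    apply(docs, 2L, paste, collapse = " ")
  })
}

#' Generate paired general/domain corpora with a planted linear geometry
#'
#' Emulates two embedding-training sources that share vocabulary: a large
#' "general" corpus (open internet style, full vocabulary) and a "domain"
#' corpus (EHR style, reduced vocabulary, sharper topic distribution). Token
#' semantics live in a latent `latent_dim`-dimensional geometry; documents
#' are drawn from a topic model (`theta ~ N(0, I)`, token probabilities
#' softmax of latent-vector/topic inner products). The domain corpus uses
#' the general latent geometry multiplied by `relation` (default identity),
#' so the linear map between the two token geometries is known and the
#' projection fit in [fit_projection()] can be tested against it.
#'
#' @param cfg a [generator_config()] (supplies vocab and seed).
#' @param n_docs documents per corpus.
#' @param doc_len tokens per document.
#' @param latent_dim dimension of the latent token geometry.
#' @param relation optional `latent_dim x latent_dim` matrix planted between
#'   the general and domain geometries (identity if NULL).
#' @param tier_cohesion in \[0, 1): how strongly the marker tokens of one
#'   tier share a common latent direction. Positive cohesion makes same-tier
#'   markers co-occur, so embedding tables trained on these corpora place
#'   them closer together than cross-tier pairs — the structure a scorer
#'   exploits.
#' @param domain_vocab_fraction fraction of the vocabulary available to the
#'   domain corpus (EHR vocabularies are smaller than open corpora).
#' @param domain_temperature softmax temperature for the domain corpus;
#'   values < 1 sharpen its token distribution.
#' @param seed seed; defaults to `cfg$seed + 1` so corpora are independent
#'   of the scored dataset drawn from the same config.
#' @return An object of class `synthetic_corpora`: list with `general` and
#'   `domain` (character vectors of documents), `shared_vocab`,
#'   `general_latents` and `domain_latents` (exact latent geometries as
#'   [embedding_table] objects, for noiseless projection tests), and
#'   `relation`.
#' @export
generate_corpora <- function(cfg, n_docs = 1000L, doc_len = 100L,
                             latent_dim = 8L, relation = NULL,
                             tier_cohesion = 0.7,
                             domain_vocab_fraction = 0.7,
                             domain_temperature = 0.8,
                             seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  latent_dim <- check_count(latent_dim, "latent_dim", min = 2L)
  if (cfg$vocab_size <= latent_dim)
    stopf("vocab_size (%d) too small for latent_dim %d", cfg$vocab_size, latent_dim)
  if (is.null(relation)) relation <- diag(latent_dim)
  relation <- as.matrix(relation)
  if (!all(dim(relation) == latent_dim))
    stopf("relation must be %d x %d", latent_dim, latent_dim)
  if (is.null(seed)) seed <- cfg$seed + 1L
  with_seed(seed, {
    vocab <- vocab_tokens(cfg)
    V <- length(vocab)
    lat <- matrix(rnorm(V * latent_dim), V, latent_dim,
                  dimnames = list(vocab, NULL))
    if (tier_cohesion < 0 || tier_cohesion >= 1)
      stopf("tier_cohesion must lie in [0, 1)")
    if (tier_cohesion > 0) {
      # each marker tier shares a common latent direction, so same-tier
      # tokens co-occur and later cluster in trained embedding tables
      tiers <- marker_tokens(cfg)
      dirs <- qr.Q(qr(matrix(rnorm(latent_dim * 2L), latent_dim, 2L)))
      rho <- tier_cohesion
      for (k2 in 1:2) {
        tok <- if (k2 == 1L) tiers$quality else tiers$deficiency
        lat[tok, ] <- sqrt(1 - rho^2) * lat[tok, , drop = FALSE] +
          rho * sqrt(latent_dim) *
            matrix(dirs[, k2], length(tok), latent_dim, byrow = TRUE)
      }
    }
    n_dom <- ceiling(domain_vocab_fraction * V)
    dom_vocab <- vocab[seq_len(n_dom)]
    lat_dom <- (lat %*% relation)[dom_vocab, , drop = FALSE]

    draw_corpus <- function(latents, temp) {
      vv <- rownames(latents)
      vapply(seq_len(n_docs), function(i) {
        theta <- rnorm(latent_dim)
        logp <- drop(latents %*% theta) / temp
        p <- exp(logp - max(logp))
        paste(sample(vv, doc_len, replace = TRUE, prob = p), collapse = " ")
      }, character(1))
    }
    general <- draw_corpus(lat, 1.0)
    domain <- draw_corpus(lat_dom, domain_temperature)
    structure(list(general = general, domain = domain,
                   shared_vocab = dom_vocab,
                   general_latents = embedding_table(vocab, lat),
                   domain_latents = embedding_table(dom_vocab, lat_dom),
                   relation = relation),
              class = "synthetic_corpora")
  })
}

#' Add synthetic model ("AI") scores to a record table
#'
#' Convenience for studying the calibration stage in isolation: pretends a
#' scoring model observed the latent quality with unbiased Gaussian noise,
#' so `ai_score = latent_quality + N(bias, noise_sd^2)`.
#'
#' @param records record data.frame with a `latent_quality` column.
#' @param noise_sd SD of the model error, score units.
#' @param bias constant offset of the model, score units (default 0).
#' @param seed RNG seed.
#' @return `records` with an `ai_score` column appended.
#' @export
simulate_ai_scores <- function(records, noise_sd = 0.5, bias = 0, seed = 1L) {
  stopifnot(is.data.frame(records), "latent_quality" %in% names(records))
  with_seed(seed, {
    records$ai_score <- records$latent_quality +
      rnorm(nrow(records), bias, noise_sd)
    records
  })
}

#' Read and write record tables and corpora
#'
#' Records are serialized as JSONL (one JSON object per line) or CSV;
#' corpora as plain text, one whitespace-tokenized document per line.
#'
#' @param records a record data.frame.
#' @param path file path.
#' @param docs character vector of documents.
#' @return Readers return the deserialized object; writers return `path`
#'   invisibly.
#' @name record_io
NULL

#' @rdname record_io
#' @export
write_records_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(records, con, verbose = FALSE, digits = NA)
  invisible(path)
}

#' @rdname record_io
#' @export
read_records_jsonl <- function(path) {
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_in(con, verbose = FALSE)
}

#' @rdname record_io
#' @export
write_corpus <- function(docs, path) {
  writeLines(docs, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname record_io
#' @export
read_corpus <- function(path) readLines(path, encoding = "UTF-8")

#' Split tokens out of a serialized record table
#'
#' @param records record data.frame with a `text` column.
#' @return list of character vectors, one per record.
#' @export
record_tokens <- function(records) strsplit(records$text, " ", fixed = TRUE)
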