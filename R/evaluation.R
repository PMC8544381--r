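#' Mean absolute error
#'
#' \deqn{MAE = \frac{\sum_{i=1}^N |y_i - \hat y_i|}{N}}
#'
#' @param y,yhat finite numeric vectors of equal nonzero length.
#' @return nonnegative scalar.
#' @export
#' @examples
#' mae(c(7, 8, 9), c(8, 8, 8))   # 2/3
mae <- function(y, yhat) {
  if (length(y) != length(yhat))
    stopf("length mismatch: %d vs %d", length(y), length(yhat))
  if (length(y) == 0L) stopf("MAE of empty vectors is undefined")
  if (any(!is.finite(y)) || any(!is.finite(yhat)))
    stopf("MAE requires finite inputs")
  mean(abs(y - yhat))
}

# Per-reviewer MAE between the expert score and a prediction column.
per_reviewer_mae <- function(records, pred_col, by = "reviewer_id") {
  err <- abs(records$expert_score - records[[pred_col]])
  tapply(err, records[[by]], mean)
}

#' Paired comparison of per-unit error vectors
#'
#' Wilcoxon signed-rank test on paired per-reviewer MAEs (exact when at
#' most 25 informative pairs and no ties, normal approximation with
#' continuity correction otherwise), or a sign test. When every difference
#' is zero the comparison is degenerate and `p = 1` is returned, flagged.
#'
#' @param raw,calibrated paired numeric vectors (>= 2 pairs).
#' @param alternative `"two.sided"` (default), `"greater"` (raw exceeds
#'   calibrated) or `"less"`.
#' @param method `"wilcoxon"` (default) or `"sign"`.
#' @return list with `p_value`, `statistic`, `method`, `n_pairs`, and
#'   logical `degenerate`.
#' @export
paired_comparison <- function(raw, calibrated,
                              alternative = c("two.sided", "greater", "less"),
                              method = c("wilcoxon", "sign")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(raw) != length(calibrated)) stopf("paired vectors differ in length")
  if (length(raw) < 2L) stopf("need at least 2 paired units")
  d <- raw - calibrated
  if (all(d == 0))
    return(list(p_value = 1, statistic = NA_real_, method = method,
                n_pairs = length(d), degenerate = TRUE))
  if (method == "sign") {
    nz <- d[d != 0]
    ht <- stats::binom.test(sum(nz > 0), length(nz), alternative = alternative)
    return(list(p_value = ht$p.value, statistic = unname(ht$statistic),
                method = method, n_pairs = length(d), degenerate = FALSE))
  }
  dz <- d[d != 0]
  if (length(dz) <= 25L) {
    ex <- exact_signed_rank(dz, alternative)
    list(p_value = ex$p_value, statistic = ex$statistic,
         method = method, n_pairs = length(d), degenerate = FALSE)
  } else {
    ht <- suppressWarnings(
      wilcox.test(raw, calibrated, paired = TRUE, alternative = alternative,
                  exact = FALSE, correct = TRUE))
    list(p_value = ht$p.value, statistic = unname(ht$statistic),
         method = method, n_pairs = length(d), degenerate = FALSE)
  }
}

# Exact signed-rank null distribution by convolution of the rank generating
# polynomial. Average ranks are doubled to integers, so tied absolute
# differences are handled exactly (stats::wilcox.test declines exactness
# under ties). Zeros must already be dropped from `d`.
exact_signed_rank <- function(d, alternative) {
  r2 <- as.integer(round(2 * rank(abs(d))))
  w_obs <- sum(r2[d > 0])
  total <- sum(r2)
  dp <- numeric(total + 1L)
  dp[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dp[seq_len(total + 1L - r)])
    dp <- (dp + shifted) / 2
  }
  p_ge <- sum(dp[(w_obs + 1L):(total + 1L)])
  p_le <- sum(dp[seq_len(w_obs + 1L)])
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(p_value = p, statistic = w_obs / 2)
}

group_stat_row <- function(records, label, pooled, cal_available) {
  revs <- unique(records$reviewer_id)
  ms <- function(x) c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else NA_real_)
  e <- ms(records$expert_score)
  r <- ms(records$ai_score)
  raw_unit <- if (pooled) abs(records$expert_score - records$ai_score)
              else as.numeric(per_reviewer_mae(records, "ai_score"))
  row <- data.frame(group = label,
                    n_records = nrow(records),
                    n_reviewers = length(revs),
                    expert_mean = e["mean"], expert_sd = e["sd"],
                    raw_mean = r["mean"], raw_sd = r["sd"],
                    raw_mae = mean(raw_unit),
                    raw_mae_sd = if (length(raw_unit) > 1L) sd(raw_unit) else NA_real_,
                    stringsAsFactors = FALSE)
  if (cal_available) {
    cst <- ms(records$calibrated_score)
    cal_unit <- if (pooled) abs(records$expert_score - records$calibrated_score)
                else as.numeric(per_reviewer_mae(records, "calibrated_score"))
    row$calibrated_mean <- cst["mean"]; row$calibrated_sd <- cst["sd"]
    row$calibrated_mae <- mean(cal_unit)
    row$calibrated_mae_sd <- if (length(cal_unit) > 1L) sd(cal_unit) else NA_real_
    row$p_value <- if (!pooled && length(raw_unit) >= 2L)
      paired_comparison(raw_unit, cal_unit)$p_value else NA_real_
  }
  rownames(row) <- NULL
  row
}

#' Grouped evaluation report
#'
#' Per-group mean ± SD of expert scores, raw model scores, calibrated
#' scores, and raw/calibrated MAE, with a paired signed-rank p-value for
#' the raw-vs-calibrated comparison in each group. MAE is aggregated
#' per-reviewer-then-averaged by default (the SD is then dispersion across
#' reviewers); `pooled = TRUE` switches to per-record pooling.
#'
#' @param records data.frame with `expert_score`, `ai_score`,
#'   `reviewer_id`, optionally `calibrated_score`, and any grouping columns.
#' @param grouping `"overall"` or the name of a column of `records`.
#' @param pooled aggregate MAE per record instead of per reviewer.
#' @return An `evaluation_report`: data.frame with one row per group plus
#'   an `"Overall"` row.
#' @export
grouped_report <- function(records, grouping = "overall", pooled = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("expert_score", "ai_score", "reviewer_id")
  if (!all(need %in% names(records)))
    stopf("records must contain %s", paste(need, collapse = ", "))
  cal <- "calibrated_score" %in% names(records)
  rows <- list(group_stat_row(records, "Overall", pooled, cal))
  if (!identical(grouping, "overall")) {
    if (!grouping %in% names(records))
      stopf("unknown grouping key `%s`", grouping)
    for (g in sort(unique(as.character(records[[grouping]])))) {
      sub <- records[records[[grouping]] == g, , drop = FALSE]
      rows <- c(rows, list(group_stat_row(sub, g, pooled, cal)))
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("evaluation_report", "data.frame"),
            grouping = grouping, pooled = pooled)
}

#' Reviewer-by-writer heatmap matrix
#'
#' Cell `(r, w)` is the mean of the chosen value over the records reviewer
#' `r` scored for writer `w`; cells with no support are `NA`, never zero.
#' Rows are ordered by reviewer department, then reviewer id. Used to spot
#' rating-bias clusters (lenient reviewer rows, over-scored writer columns).
#'
#' @param records record data.frame; needs `reviewer_id`, `writer_id` and
#'   the score columns implied by `value`/`score_source`.
#' @param value `"mean_score"` or `"mean_abs_error"` (|expert - source|).
#' @param score_source which score feeds the cells: `"expert"`,
#'   `"raw"` (`ai_score`) or `"calibrated"`.
#' @param reviewer_departments optional named vector mapping reviewer id to
#'   department; by default the modal department of each reviewer's records.
#' @return An object of class `heatmap_matrix`: list with `values`,
#'   `support` (record counts), and `reviewer_departments`.
#' @export
reviewer_writer_heatmap <- function(records,
                                    value = c("mean_score", "mean_abs_error"),
                                    score_source = c("expert", "raw", "calibrated"),
                                    reviewer_departments = NULL) {
  value <- match.arg(value)
  score_source <- match.arg(score_source)
  col <- switch(score_source, expert = "expert_score", raw = "ai_score",
                calibrated = "calibrated_score")
  if (!col %in% names(records)) stopf("records lack column `%s`", col)
  v <- if (value == "mean_score") records[[col]]
       else abs(records$expert_score - records[[col]])
  r <- as.character(records$reviewer_id); w <- as.character(records$writer_id)
  if (is.null(reviewer_departments)) {
    reviewer_departments <- tapply(as.character(records$department), r,
                                   function(d) names(sort(table(d), decreasing = TRUE))[1L])
  }
  vals <- tapply(v, list(r, w), mean)
  supp <- tapply(v, list(r, w), length)
  supp[is.na(supp)] <- 0
  ord <- order(reviewer_departments[rownames(vals)], rownames(vals))
  vals <- vals[ord, , drop = FALSE]
  supp <- supp[ord, , drop = FALSE]
  structure(list(values = vals, support = supp,
                 reviewer_departments = reviewer_departments[rownames(vals)],
                 value = value, score_source = score_source),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("<heatmap_matrix> %s of %s scores: %d reviewers x %d writers (%d empty cells)\n",
              x$value, x$score_source, nrow(x$values), ncol(x$values),
              sum(x$support == 0)))
  invisible(x)
}

#' Write a heatmap matrix as TSV
#'
#' Emits two tab-separated matrices (values and support counts) with row
#' and column keys; empty cells are written as `NA`.
#'
#' @param hm a [reviewer_writer_heatmap()] result.
#' @param path base path; `path` gets the values, `<path>.support` counts.
#' @export
write_heatmap_tsv <- function(hm, path) {
  stopifnot(inherits(hm, "heatmap_matrix"))
  utils::write.table(hm$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(hm$support, paste0(path, ".support"), sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Summaries for reviewer/writer blocks
#'
#' Blocks are named groups of reviewers and writers (the rectangular
#' regions one picks out of the reviewer-by-writer heatmap). A record
#' belongs to block `b` when both its reviewer and its writer are assigned
#' to `b`; unassigned pairs are excluded. Each block gets the grouped
#' report columns (score means ± SD, raw and calibrated MAE, paired
#' p-value).
#'
#' @param records record data.frame (as for [grouped_report()]).
#' @param assignments data.frame with columns `entity_id` (reviewer or
#'   writer ids) and `block`.
#' @param pooled see [grouped_report()].
#' @return An `evaluation_report` with one row per block (no overall row).
#' @export
block_summary <- function(records, assignments, pooled = FALSE) {
  stopifnot(is.data.frame(assignments),
            all(c("entity_id", "block") %in% names(assignments)))
  lookup <- setNames(as.character(assignments$block),
                     as.character(assignments$entity_id))
  rb <- lookup[as.character(records$reviewer_id)]
  wb <- lookup[as.character(records$writer_id)]
  blk <- ifelse(!is.na(rb) & !is.na(wb) & rb == wb, rb, NA_character_)
  labels <- sort(unique(as.character(assignments$block)))
  rows <- lapply(labels, function(b) {
    sub <- records[!is.na(blk) & blk == b, , drop = FALSE]
    if (nrow(sub) == 0L) stopf("block `%s` contains no records", b)
    group_stat_row(sub, b, pooled, "calibrated_score" %in% names(records))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("evaluation_report", "data.frame"),
            grouping = "block", pooled = pooled)
}

#' Heuristic block suggestion by k-means on heatmap rows
#'
#' Convenience helper that clusters reviewers by their heatmap row profiles
#' (k-means after mean-imputing empty cells) and assigns each writer to the
#' reviewer-cluster that scores them highest. This is a rough automated
#' stand-in for picking blocks out of the heatmap by eye, not a published
#' procedure; treat its output as a starting point.
#'
#' @param hm a [reviewer_writer_heatmap()] result.
#' @param k number of blocks.
#' @param seed RNG seed for k-means starts.
#' @return data.frame with `entity_id` and `block` (labels `"B1"...`),
#'   covering reviewers and writers, suitable for [block_summary()].
#' @export
suggest_blocks <- function(hm, k = 4L, seed = 1L) {
  stopifnot(inherits(hm, "heatmap_matrix"))
  k <- check_count(k, "k", min = 2L)
  M <- hm$values
  M[is.na(M)] <- mean(M, na.rm = TRUE)
  with_seed(seed, {
    km <- kmeans(M, centers = min(k, nrow(M) - 1L), nstart = 5L)
    rb <- paste0("B", km$cluster)
    cb <- paste0("B", apply(M, 2L, function(col)
      which.max(tapply(col, km$cluster, mean))))
    data.frame(entity_id = c(rownames(M), colnames(M)),
               block = c(rb, cb), stringsAsFactors = FALSE)
  })
}

#' Group reviewers into quartiles of calibrated MAE
#'
#' Reviewers are ranked by their calibrated-score MAE and split at the
#' 25/50/75 empirical percentiles into Q1 (best) through Q4 (worst). Ties
#' are broken by a stable sort on reviewer id, so quartile sizes differ by
#' at most one. Per-quartile summaries of expert, raw and calibrated
#' scores and MAEs are returned alongside the assignment.
#'
#' @param records record data.frame with `expert_score`, `ai_score`,
#'   `calibrated_score`, `reviewer_id`; needs >= 4 reviewers.
#' @return An object of class `quartile_grouping`: list with `assignments`
#'   (reviewer_id, calibrated_mae, quartile) and `summary` (per-quartile
#'   mean ± SD table).
#' @export
quartile_grouping <- function(records) {
  need <- c("expert_score", "ai_score", "calibrated_score", "reviewer_id")
  if (!all(need %in% names(records)))
    stopf("records must contain %s", paste(need, collapse = ", "))
  cmae <- per_reviewer_mae(records, "calibrated_score")
  if (length(cmae) < 4L)
    stopf("quartile grouping needs at least 4 reviewers (got %d)", length(cmae))
  ids <- names(cmae)
  ord <- order(cmae, ids)
  n <- length(cmae)
  qt <- integer(n)
  qt[ord] <- ceiling(4 * seq_len(n) / n)
  assignments <- data.frame(reviewer_id = ids,
                            calibrated_mae = as.numeric(cmae),
                            quartile = paste0("Q", qt),
                            stringsAsFactors = FALSE)
  rmae <- per_reviewer_mae(records, "ai_score")
  emean <- tapply(records$expert_score, records$reviewer_id, mean)
  amean <- tapply(records$ai_score, records$reviewer_id, mean)
  cmean <- tapply(records$calibrated_score, records$reviewer_id, mean)
  ms <- function(x) sprintf_stats(mean(x), if (length(x) > 1) sd(x) else NA)
  summ <- do.call(rbind, lapply(paste0("Q", 1:4), function(qq) {
    sel <- assignments$quartile == qq
    idq <- assignments$reviewer_id[sel]
    data.frame(quartile = qq, n_reviewers = sum(sel),
               expert_mean = mean(emean[idq]), expert_sd = sdna(emean[idq]),
               raw_mean = mean(amean[idq]), raw_sd = sdna(amean[idq]),
               calibrated_mean = mean(cmean[idq]), calibrated_sd = sdna(cmean[idq]),
               raw_mae = mean(rmae[idq]), raw_mae_sd = sdna(rmae[idq]),
               calibrated_mae = mean(cmae[idq]), calibrated_mae_sd = sdna(cmae[idq]),
               stringsAsFactors = FALSE)
  }))
  structure(list(assignments = assignments, summary = summ),
            class = "quartile_grouping")
}

sdna <- function(x) if (length(x) > 1L) sd(x) else NA_real_
sprintf_stats <- function(m, s) sprintf("%.2f ± %.2f", m, s)

#' @export
print.quartile_grouping <- function(x, ...) {
  cat("<quartile_grouping>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
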