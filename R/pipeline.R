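#' Split a record table into training and testing sets
#'
#' Either on a timestamp threshold (`by_time_field`: train = records at or
#' before the threshold, emulating a by-period study design) or as a seeded
#' random fraction (`by_fraction`: `floor(fraction * n)` records train —
#' rounding down — the rest test). The two sides are always disjoint and
#' exhaustive; an empty side is an error.
#'
#' @param records record data.frame.
#' @param rule `"by_time_field"` or `"by_fraction"`.
#' @param time_field column holding an orderable timestamp.
#' @param threshold timestamp threshold (train: `time <= threshold`).
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed for `by_fraction`.
#' @return list with `train` and `test` data.frames.
#' @export
split_dataset <- function(records, rule = c("by_time_field", "by_fraction"),
                          time_field = "time", threshold = NULL,
                          fraction = NULL, seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(records))
  if (rule == "by_time_field") {
    if (!time_field %in% names(records))
      stopf("time field `%s` not found", time_field)
    if (is.null(threshold)) stopf("by_time_field requires a threshold")
    tr <- records[[time_field]] <= threshold
  } else {
    if (is.null(fraction) || fraction <= 0 || fraction >= 1)
      stopf("by_fraction requires fraction in (0, 1)")
    n_train <- floor(fraction * nrow(records))
    tr <- rep(FALSE, nrow(records))
    with_seed(seed, tr[sample.int(nrow(records), n_train)] <- TRUE)
  }
  if (!any(tr)) stopf("training side of the split is empty")
  if (all(tr)) stopf("testing side of the split is empty")
  list(train = records[tr, , drop = FALSE], test = records[!tr, , drop = FALSE])
}

#' Configuration for the end-to-end scoring pipeline
#'
#' Bundles the stage configurations: data generation, corpora and
#' embeddings, scorer training, the mixed-model formula, the train/test
#' split, and evaluation options. A single `seed` drives every stage
#' (per-stage streams are derived by fixed offsets), so one config plus one
#' seed reproduces every artifact.
#'
#' @param generator a [generator_config()].
#' @param scorer a [scorer_config()].
#' @param formula a [formula_spec()].
#' @param embedding list: `d` (per-source embedding dimension), `window`.
#' @param corpora list passed to [generate_corpora()] (`n_docs`, `doc_len`,
#'   `latent_dim`, `domain_vocab_fraction`, `domain_temperature`).
#' @param split list: `rule`, plus `fraction` (train share; under the
#'   time rule the threshold is the fraction quantile of the time field).
#' @param calibrate run the mixed-model calibration stage.
#' @param calibration_mode `"holdout"`: fit the LMM and reviewer BLUPs on
#'   training-period residuals only; `"in_sample"`: refit on the test
#'   period's expert/AI pairs before modifying test scores.
#' @param pooled_mae evaluate MAE pooled per record instead of per reviewer.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(n_records = 1000L),
                            scorer = scorer_config(hidden_dim = 16L),
                            formula = formula_spec(),
                            embedding = list(d = 8L, window = 5L),
                            corpora = list(n_docs = 600L, doc_len = 100L,
                                           latent_dim = 8L,
                                           domain_vocab_fraction = 0.7,
                                           domain_temperature = 0.8),
                            split = list(rule = "by_time_field", fraction = 1/3),
                            calibrate = TRUE,
                            calibration_mode = c("holdout", "in_sample"),
                            pooled_mae = FALSE,
                            seed = 1L) {
  calibration_mode <- match.arg(calibration_mode)
  stopifnot(inherits(generator, "generator_config"),
            inherits(scorer, "scorer_config"),
            inherits(formula, "formula_spec"))
  structure(list(generator = generator, scorer = scorer, formula = formula,
                 embedding = embedding, corpora = corpora, split = split,
                 calibrate = isTRUE(calibrate),
                 calibration_mode = calibration_mode,
                 pooled_mae = isTRUE(pooled_mae),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the corresponding
#' [pipeline_config()] defaults; nested `generator`, `scorer`, `formula`
#' blocks are passed to their constructors.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("reading YAML configs requires the `yaml` package")
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$generator)) args$generator <- do.call(generator_config, y$generator)
  if (!is.null(y$scorer)) args$scorer <- do.call(scorer_config, y$scorer)
  if (!is.null(y$formula)) args$formula <- do.call(formula_spec, y$formula)
  for (nm in intersect(names(y), c("embedding", "corpora", "split", "calibrate",
                                   "calibration_mode", "pooled_mae", "seed")))
    args[[nm]] <- y[[nm]]
  do.call(pipeline_config, args)
}

stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[notescore] %s", sprintf(fmt, ...)))
}

write_report_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full scoring pipeline
#'
#' Orchestrates the train/test flow end to end: simulate a scored-record
#' corpus; build general and domain corpora and embedding tables; fit the
#' projection and concatenate the original and projected general tables (so
#' the scorer sees both embedding sources over the full open vocabulary);
#' train the recurrent scorer on the training period; predict scores for
#' both periods; fit the mixed model and reviewer BLUPs (training period
#' under `"holdout"`, test period under `"in_sample"`); calibrate the test
#' scores; and write evaluation reports, heatmaps and quartile diagnostics.
#' Every artifact lands in `out_dir` along with a `manifest.json` (seed,
#' config, package version, file checksums). A rerun with the same config
#' and seed reproduces every file byte for byte.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir artifact directory (created if missing).
#' @param verbose emit per-stage progress messages.
#' @return Invisibly, a list with the split records, fitted objects and
#'   reports; on failure the offending stage is named in the error.
#' @export
run_pipeline <- function(cfg, out_dir, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    t0 <- proc.time()[["elapsed"]]
    gen <- cfg$generator
    gen$seed <- cfg$seed
    dat <- generate_scoring_dataset(gen)
    write_records_jsonl(dat$records, file.path(out_dir, "records.jsonl"))
    write.csv(dat$truth$reviewers, file.path(out_dir, "truth_reviewers.csv"),
              row.names = FALSE)
    write.csv(dat$truth$writers, file.path(out_dir, "truth_writers.csv"),
              row.names = FALSE)
    stage_msg(verbose, "simulate: %d records (%.1fs)", nrow(dat$records),
              proc.time()[["elapsed"]] - t0)

    stage <- "embed"
    t0 <- proc.time()[["elapsed"]]
    corp <- do.call(generate_corpora,
                    c(list(cfg = gen, seed = cfg$seed + 1000L), cfg$corpora))
    write_corpus(corp$general, file.path(out_dir, "corpus_general.txt"))
    write_corpus(corp$domain, file.path(out_dir, "corpus_domain.txt"))
    d_emb <- cfg$embedding$d
    tab_gen <- train_embeddings(corp$general, d = d_emb,
                                window = cfg$embedding$window)
    tab_dom <- train_embeddings(corp$domain, d = d_emb,
                                window = cfg$embedding$window)
    proj <- fit_projection(tab_gen, tab_dom)
    tab_proj <- project_table(tab_gen, proj)
    tab_full <- concat_embeddings(list(tab_gen, tab_proj))
    write_word2vec(tab_gen, file.path(out_dir, "embeddings_general.vec"))
    write_word2vec(tab_dom, file.path(out_dir, "embeddings_domain.vec"))
    write_word2vec(tab_full, file.path(out_dir, "embeddings_combined.vec"))
    write_projection(proj, file.path(out_dir, "projection.tsv"))
    stage_msg(verbose, "embed: %d-symbol tables, projection residual %.3f (%.1fs)",
              length(tab_full$vocab), proj$fit_residual,
              proc.time()[["elapsed"]] - t0)

    stage <- "split"
    thr <- as.numeric(quantile(dat$records$time, cfg$split$fraction, type = 1))
    parts <- if (identical(cfg$split$rule, "by_time_field"))
      split_dataset(dat$records, "by_time_field", threshold = thr)
    else split_dataset(dat$records, "by_fraction",
                       fraction = cfg$split$fraction, seed = cfg$seed + 2000L)

    stage <- "train"
    t0 <- proc.time()[["elapsed"]]
    scfg <- cfg$scorer
    scfg$seed <- cfg$seed + 3000L
    scfg$score_min <- gen$score_min; scfg$score_max <- gen$score_max
    model <- train_scorer(parts$train, tab_full, scfg)
    save_scorer(model, file.path(out_dir, "scorer.json"))
    stage_msg(verbose, "train: %d epochs, final loss %.4f (%.1fs)",
              scfg$epochs, tail(model$history, 1L),
              proc.time()[["elapsed"]] - t0)

    stage <- "predict"
    t0 <- proc.time()[["elapsed"]]
    parts$train$ai_score <- predict_scores(model, parts$train)
    parts$test$ai_score <- predict_scores(model, parts$test)
    stage_msg(verbose, "predict: %d train + %d test records (%.1fs)",
              nrow(parts$train), nrow(parts$test),
              proc.time()[["elapsed"]] - t0)

    fit <- NULL; blups <- NULL
    if (cfg$calibrate) {
      stage <- "calibrate"
      t0 <- proc.time()[["elapsed"]]
      cal_data <- if (cfg$calibration_mode == "holdout") parts$train else parts$test
      designs <- build_designs(cal_data, cfg$formula)
      fit <- estimate_lmm(designs)
      blups <- compute_blups(fit, designs)
      cal <- calibrate_scores(fit, blups, parts$test)
      parts$test$calibrated_score <- cal$calibrated_score
      parts$test$population_level <- cal$population_level
      write.csv(cal, file.path(out_dir, "calibrated_scores.csv"),
                row.names = FALSE)
      fit_report <- list(B = as.list(fit$B), G = fit$G, sigma2 = fit$sigma2,
                         loglik = fit$loglik, iterations = fit$iterations,
                         mode = cfg$calibration_mode,
                         blups = lapply(blups, function(b) as.list(b$blup)))
      jsonlite::write_json(fit_report, file.path(out_dir, "lmm_fit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stage_msg(verbose, "calibrate: %d clusters, sigma^2 = %.3f (%.1fs)",
                fit$n_clusters, fit$sigma2, proc.time()[["elapsed"]] - t0)
    }
    utils::write.csv(parts$test[, setdiff(names(parts$test), "text")],
                     file.path(out_dir, "scored_test_records.csv"),
                     row.names = FALSE)

    stage <- "evaluate"
    t0 <- proc.time()[["elapsed"]]
    rep_overall <- grouped_report(parts$test, "overall", pooled = cfg$pooled_mae)
    rep_div <- grouped_report(parts$test, "division", pooled = cfg$pooled_mae)
    rep_dept <- grouped_report(parts$test, "department", pooled = cfg$pooled_mae)
    write_report_tsv(rep_overall, file.path(out_dir, "report_overall.tsv"))
    write_report_tsv(rep_div, file.path(out_dir, "report_division.tsv"))
    write_report_tsv(rep_dept, file.path(out_dir, "report_department.tsv"))
    hm_score <- reviewer_writer_heatmap(parts$test, "mean_score", "expert")
    write_heatmap_tsv(hm_score, file.path(out_dir, "heatmap_expert_score.tsv"))
    qg <- NULL
    if (cfg$calibrate) {
      hm_mae <- reviewer_writer_heatmap(parts$test, "mean_abs_error", "calibrated")
      write_heatmap_tsv(hm_mae, file.path(out_dir, "heatmap_calibrated_mae.tsv"))
      qg <- quartile_grouping(parts$test)
      write.csv(qg$assignments, file.path(out_dir, "quartile_assignments.csv"),
                row.names = FALSE)
      write_report_tsv(qg$summary, file.path(out_dir, "quartile_summary.tsv"))
    }
    stage_msg(verbose, "evaluate: overall raw MAE %.3f%s (%.1fs)",
              rep_overall$raw_mae[1L],
              if (cfg$calibrate)
                sprintf(", calibrated MAE %.3f", rep_overall$calibrated_mae[1L])
              else "",
              proc.time()[["elapsed"]] - t0)

    stage <- "manifest"
    files <- sort(setdiff(list.files(out_dir), "manifest.json"))
    manifest <- list(
      package = "notescore",
      version = as.character(packageVersion("notescore")),
      seed = cfg$seed,
      calibration_mode = if (cfg$calibrate) cfg$calibration_mode else "off",
      config = unclass_deep(cfg),
      files = as.list(setNames(
        unname(tools::md5sum(file.path(out_dir, files))), files))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(records = dat, parts = parts, model = model, fit = fit,
                   blups = blups, reports = list(overall = rep_overall,
                                                 division = rep_div,
                                                 department = rep_dept),
                   quartiles = qg, out_dir = out_dir))
  }, error = function(e) {
    stopf("pipeline failed at stage `%s`: %s", stage, conditionMessage(e))
  })
  result
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
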