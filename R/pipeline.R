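# End-to-end pipeline: generate -> annotate -> pairs -> split -> pretrain ->
# train -> score -> screen -> evaluate, with every stage seeded from one
# global seed and every CSV artifact provenance-stamped. Re-running with the
# same (config, seed) reproduces all CSVs byte-identically.

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
  log(sprintf("stage=%s elapsed=%.2fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the whole screening pipeline
#'
#' Executes the full workflow on a synthetic dataset: scene generation,
#' simulated-annotator ranking session, pair extraction, item-level split,
#' optional segmentation pretraining, Siamese ranking training, deviation
#' scoring, threshold screening, and held-out evaluation. All artifacts are
#' written under `out_dir` as provenance-stamped CSVs (plus a JSON session
#' log and model checkpoint).
#'
#' @param config A [meal_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; each stage derives its own via [stage_seed()].
#' @param n_items Number of synthetic meals to generate.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory results and artifact
#'   paths (`evaluation`, `scores`, `decisions`, `model`, `paths`).
#' @export
pipeline_run <- function(config = meal_config(), out_dir, seed = 1L,
                         n_items = 120L, quiet = FALSE) {
  stopifnot(inherits(config, "meal_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  logf <- function(line) {
    log_lines <<- c(log_lines, paste0("seed=", seed, " ", line))
    if (!quiet) message(line)
  }
  hash <- config_hash(config)
  logf(sprintf("pipeline start config_hash=%s n_items=%d", hash, n_items))

  meals <- .stage("generate", logf,
                  generate_meals(n_items, config, stage_seed(seed, "generate")))
  write_meals(meals, file.path(out_dir, "data"))

  annotator <- simulated_annotator(config$noise_sd, config$tie_tolerance,
                                   seed = stage_seed(seed, "annotate"))
  session <- .stage("annotate", logf, {
    oracle <- latent_oracle(stats::setNames(meals$latent, meals$id), annotator,
                            seed = stage_seed(seed, "annotate"))
    run_session(meals$id, oracle, n_c = config$n_c,
                seed = stage_seed(seed, "session"))
  })
  write_ranking(session$ranking, file.path(out_dir, "ranking.csv"),
                config, seed)
  jsonlite::write_json(session$log, file.path(out_dir, "session_log.json"),
                       auto_unbox = TRUE, digits = NA)

  pairs <- .stage("pairs", logf,
                  extract_pairs(session$ranking, config$max_pairs,
                                seed = stage_seed(seed, "pairs")))
  write_pairs(pairs, file.path(out_dir, "pairs.csv"), config, seed)

  sp <- .stage("split", logf,
               split_dataset(pairs, session$ranking, config$train_fraction,
                             seed = stage_seed(seed, "split")))
  write_pairs(sp$train_pairs, file.path(out_dir, "train_pairs.csv"), config, seed)
  write_meal_csv(tibble::tibble(item_id = sp$test_items),
                 file.path(out_dir, "test_items.csv"), config, seed)

  train_meals <- meals[meals$id %in% sp$train_items, ]
  extractor <- NULL
  if (config$pretrain_mode) {
    extractor <- .stage("pretrain", logf,
                        pretrain_extractor(train_meals, config,
                                           seed = stage_seed(seed, "pretrain")))
    logf(sprintf("pretrain pixel accuracy=%.4f",
                 pretrain_accuracy(extractor, train_meals)))
  }

  model <- .stage("train", logf,
                  train_ranking(sp$train_pairs, train_meals, config,
                                extractor = extractor,
                                seed = stage_seed(seed, "train")))
  save_model(model, file.path(out_dir, "model.json"))

  scores <- .stage("score", logf, {
    raw <- score_meals(meals, model)
    deviation_scores(raw, transform = config$score_transform)
  })
  write_scores(scores, file.path(out_dir, "scores.csv"), config, seed)

  th <- threshold_for_quantile(scores$s, config$screen_k)
  decisions <- .stage("screen", logf, screen_meals(scores, th))
  write_meal_csv(tibble::as_tibble(decisions),
                 file.path(out_dir, "decisions.csv"), config, seed)

  evaluation <- .stage("evaluate", logf, {
    # reference = the annotator's ranking, as in the screening workflow
    test_df <- tibble::tibble(
      item_id = sp$test_items,
      truth = -session$ranking$rank[match(sp$test_items,
                                          session$ranking$item_id)],
      estimate = scores$raw[match(sp$test_items, scores$item_id)]
    )
    ev <- evaluate_ranking(test_df, truth, estimate)
    n <- nrow(test_df)
    o_ref <- .order_vector(test_df$truth, test_df$item_id)
    unhealthy <- o_ref > n - floor(config$screen_k * n / 100)
    test_s <- scores$s[match(sp$test_items, scores$item_id)]
    det <- detection_eval(unhealthy, estimate = test_s,
                          th = threshold_for_quantile(test_s, config$screen_k))
    dplyr::bind_cols(ev,
                     tibble::tibble(detection_accuracy = det$accuracy,
                                    auc = det$auc, n_test = n,
                                    n_train = length(sp$train_items)))
  })
  write_meal_csv(evaluation, file.path(out_dir, "evaluation.csv"), config, seed)
  logf("pipeline done")
  writeLines(log_lines, log_path)

  invisible(list(
    evaluation = evaluation, scores = scores, decisions = decisions,
    model = model, session = session,
    paths = list(
      data = file.path(out_dir, "data", "manifest.csv"),
      ranking = file.path(out_dir, "ranking.csv"),
      pairs = file.path(out_dir, "pairs.csv"),
      scores = file.path(out_dir, "scores.csv"),
      decisions = file.path(out_dir, "decisions.csv"),
      evaluation = file.path(out_dir, "evaluation.csv"),
      model = file.path(out_dir, "model.json"),
      log = log_path
    )
  ))
}
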