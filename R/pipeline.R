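#' Experiment configuration
#'
#' One object describing a full experiment: which screening task collapses
#' the risk taxonomy, where the two corpora come from (a seeded generator
#' configuration, post-level tibbles, or JSONL paths), the model and
#' training settings, the split specification, and optional auxiliary
#' lexicon features.
#'
#' @param task `"flagged"` or `"urgent"`.
#' @param generator A [generator_config()] used to simulate the paired
#'   corpora, or `NULL` when corpora are supplied directly.
#' @param corpus_a,corpus_b Post-level tibbles or JSONL paths with a
#'   `split` column/field (`"train"`/`"test"`); ignored when `generator`
#'   is given.
#' @param model Named list of [model_config()] overrides (e.g.
#'   `list(embed_dim = 16)`); `vocab_size`, `max_len`, `aux_units` and
#'   `aux_dim` are filled in by the pipeline.
#' @param training A [train_config()].
#' @param split A [split_spec()].
#' @param aux_preset Optional [load_preset()] name; requires `lexicon`.
#' @param lexicon An [lexicon()] object or JSON path with term sets for
#'   the preset categories.
#' @param aux_units Hidden units of the auxiliary dense layer; defaults
#'   per preset to the published settings (flagged14: 8, urgent6: 16,
#'   crossplatform10: 32).
#' @param max_len Encoded sequence length; `NULL` uses the 95th
#'   percentile of training document lengths capped at `max_len_cap`.
#' @param max_len_cap Upper bound for the automatic `max_len`.
#' @param vocab_max_size Vocabulary cap (including reserved indices).
#' @param extra_test_sets Named list of additional held-out test sets,
#'   each a list with `corpus_a` and `corpus_b` (tibbles or paths),
#'   evaluated with the trained ensemble without retraining.
#' @param seed Master seed; generator, alignment, splits and training
#'   seeds all derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(task = c("flagged", "urgent"),
                              generator = NULL,
                              corpus_a = NULL, corpus_b = NULL,
                              model = list(),
                              training = train_config(),
                              split = split_spec(),
                              aux_preset = NULL,
                              lexicon = NULL,
                              aux_units = NULL,
                              max_len = NULL,
                              max_len_cap = 400L,
                              vocab_max_size = 20000L,
                              extra_test_sets = list(),
                              seed = 1L) {
  task <- match.arg(task)
  if (is.null(generator) && (is.null(corpus_a) || is.null(corpus_b))) {
    stop("either a generator config or both corpora are required",
         call. = FALSE)
  }
  if (!is.null(aux_preset) && is.null(lexicon)) {
    stop("aux_preset requires a lexicon", call. = FALSE)
  }
  if (is.null(aux_units) && !is.null(aux_preset)) {
    aux_units <- switch(aux_preset, flagged14 = 8L, urgent6 = 16L,
                        crossplatform10 = 32L)
  }
  structure(
    list(task = task, generator = generator, corpus_a = corpus_a,
         corpus_b = corpus_b, model = model, training = training,
         split = split, aux_preset = aux_preset, lexicon = lexicon,
         aux_units = aux_units, max_len = max_len,
         max_len_cap = as.integer(max_len_cap),
         vocab_max_size = as.integer(vocab_max_size),
         extra_test_sets = extra_test_sets, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

resolve_corpus <- function(x) {
  if (is.character(x)) read_corpus_jsonl(x) else tibble::as_tibble(x)
}

preprocess_corpus <- function(corpus, min_tokens) {
  platform <- corpus$platform[1] %||% "reddit"
  if (!platform %in% c("reddit", "twitter", "synthetic")) {
    platform <- "reddit"
  }
  cc <- cleaning_config(platform, min_tokens = min_tokens)
  corpus |>
    build_user_documents(cc) |>
    filter_min_tokens(cc$min_tokens)
}

binary_labels <- function(docs, task_name) {
  collapse_risk(docs$label, task_name)
}

encode_pair <- function(aligned, vocab, max_len, aux_ctx = NULL) {
  x_a <- encode_and_pad(aligned$tokens_a, vocab, max_len)
  x_b <- encode_and_pad(aligned$tokens_b, vocab, max_len)
  aux_a <- aux_b <- NULL
  if (!is.null(aux_ctx)) {
    feat <- function(tokens, scaler) {
      f <- score_categories(tibble::tibble(
        user_id = as.character(seq_along(tokens)), tokens = tokens
      ), aux_ctx$lexicon)
      as_feature_matrix(apply_scaler(scaler, f))
    }
    aux_a <- feat(aligned$tokens_a, aux_ctx$scaler_a)
    aux_b <- feat(aligned$tokens_b, aux_ctx$scaler_b)
  }
  mtl_dataset(x_a = x_a, y_a = aligned$label, x_b = x_b,
              y_b = aligned$label, aux_a = aux_a, aux_b = aux_b,
              user_id_a = aligned$user_id_a,
              user_id_b = aligned$user_id_b)
}

#' Assemble the encoded train/test datasets of an experiment
#'
#' Runs the data side of the experiment chain deterministically from the
#' configuration seed: simulate or load the two corpora, preprocess and
#' filter each, collapse the risk taxonomy to the task's binary labels,
#' align training pairs positive-with-positive, build the pooled
#' vocabulary from both tasks' training documents, choose the sequence
#' length, encode, and (optionally) featurise the lexicon categories with
#' a train-fitted scaler.
#'
#' @param cfg An [experiment_config()].
#' @return A list with `train_ds`, `test_ds`, `model_cfg`, `vocab`,
#'   `max_len`, `task`, `manifest` (seeds, counts, split/alignment
#'   bookkeeping) and `aux_ctx`.
#' @export
prepare_experiment_data <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!is.null(cfg$generator)) {
    gen <- cfg$generator
    gen$seed <- cfg$seed
    pair <- generate_corpus_pair(gen)
    corpus_a <- pair$corpus_a
    corpus_b <- pair$corpus_b
    min_tokens <- gen$min_tokens
    gen_lexicon <- pair$lexicon
  } else {
    corpus_a <- resolve_corpus(cfg$corpus_a)
    corpus_b <- resolve_corpus(cfg$corpus_b)
    min_tokens <- NULL
    gen_lexicon <- NULL
  }

  docs_a <- preprocess_corpus(corpus_a, min_tokens)
  docs_b <- preprocess_corpus(corpus_b, min_tokens)
  docs_a$.y <- binary_labels(docs_a, cfg$task)
  docs_b$.y <- binary_labels(docs_b, "disorder")

  part <- function(docs, s) {
    d <- docs[docs$split == s, , drop = FALSE]
    dplyr::select(d, "user_id", "tokens", "n_tokens", label = ".y")
  }
  align_train <- align_tasks(part(docs_a, "train"), part(docs_b, "train"),
                             seed = cfg$seed + 300L)
  align_test <- align_tasks(part(docs_a, "test"), part(docs_b, "test"),
                            seed = cfg$seed + 301L)

  vocab <- build_vocabulary(align_train$tokens_a, align_train$tokens_b,
                            max_size = cfg$vocab_max_size)
  max_len <- cfg$max_len %||% suggest_max_len(
    c(lengths(align_train$tokens_a), lengths(align_train$tokens_b)),
    cap = cfg$max_len_cap
  )

  aux_ctx <- NULL
  if (!is.null(cfg$aux_preset)) {
    lex <- if (is.character(cfg$lexicon)) read_lexicon(cfg$lexicon)
           else cfg$lexicon
    if (is.null(lex)) lex <- gen_lexicon
    lex <- apply_preset(lex, cfg$aux_preset)
    train_feat <- function(tokens) {
      score_categories(tibble::tibble(user_id = as.character(seq_along(tokens)),
                                      tokens = tokens), lex)
    }
    aux_ctx <- list(
      lexicon = lex,
      scaler_a = fit_scaler(train_feat(align_train$tokens_a)),
      scaler_b = fit_scaler(train_feat(align_train$tokens_b))
    )
  }

  train_ds <- encode_pair(align_train, vocab, max_len, aux_ctx)
  test_ds <- encode_pair(align_test, vocab, max_len, aux_ctx)

  model_args <- modifyList(
    list(vocab_size = length(vocab) + 2L, max_len = max_len),
    cfg$model
  )
  model_args$vocab_size <- length(vocab) + 2L
  model_args$max_len <- max_len
  if (!is.null(cfg$aux_preset)) {
    model_args$aux_units <- cfg$aux_units
    model_args$aux_dim <- length(aux_ctx$lexicon$categories)
  }
  model_cfg <- do.call(model_config, model_args)

  list(
    train_ds = train_ds, test_ds = test_ds, model_cfg = model_cfg,
    vocab = vocab, max_len = max_len, task = cfg$task,
    aux_ctx = aux_ctx,
    manifest = list(
      seed = cfg$seed,
      task = cfg$task,
      min_tokens = min_tokens,
      n_train_pairs = train_ds$n,
      n_test_pairs = test_ds$n,
      vocab_size = length(vocab) + 2L,
      max_len = max_len,
      align_seed_train = cfg$seed + 300L,
      align_seed_test = cfg$seed + 301L
    )
  )
}

metric_fields <- function(metrics_s, metrics_m) {
  list(
    Ps = metrics_s$macro_precision, Pm = metrics_m$macro_precision,
    Rs = metrics_s$macro_recall, Rm = metrics_m$macro_recall,
    F1s = metrics_s$macro_f1, F1m = metrics_m$macro_f1,
    ACCs = metrics_s$accuracy, ACCm = metrics_m$accuracy,
    AUCs = metrics_s$macro_auc, AUCm = metrics_m$macro_auc
  )
}

evaluate_pair_predictions <- function(pred, ds, test_set = "test") {
  m_s <- metrics_report(ds$y_a, pred$labels[[1]], pred$probs[[1]][, 2],
                        task = "suicide")
  m_m <- metrics_report(ds$y_b, pred$labels[[2]], pred$probs[[2]][, 2],
                        task = "disorder")
  list(
    metrics = dplyr::bind_cols(tibble::tibble(test_set = test_set),
                               dplyr::bind_rows(m_s, m_m)),
    fields = metric_fields(m_s, m_m)
  )
}

#' Run a full multi-task experiment
#'
#' Executes the whole chain deterministically from the configuration
#' seed: data assembly ([prepare_experiment_data()]), stratified shuffle
#' splits, one multi-task model trained per split, model-averaging
#' ensemble inference on the held-out test pairs, and metric reporting in
#' the standard vocabulary (Ps, Pm, Rs, Rm, F1s, F1m, ACCs, ACCm, AUCs,
#' AUCm; `s` = suicide-ideation task, `m` = mental-disorder task). Extra
#' held-out test sets are evaluated with the already-trained ensemble,
#' without retraining.
#'
#' @param cfg An [experiment_config()].
#' @param data Optional pre-built [prepare_experiment_data()] result (to
#'   share one dataset across experiment variants).
#' @return An object of class `mtl_experiment`: `results` (named metric
#'   list per test set), `metrics` (tidy tibble), `ensemble`, `data`,
#'   `manifest`.
#' @export
run_experiment <- function(cfg, data = NULL) {
  if (is.null(data)) data <- prepare_experiment_data(cfg)
  splits <- stratified_shuffle_splits(data$train_ds$y_a, cfg$split)
  ensemble <- train_ensemble(data$train_ds, splits, data$model_cfg,
                             cfg$training, kind = "mtl")
  pred <- predict_ensemble(ensemble, data$test_ds)
  ev <- evaluate_pair_predictions(pred, data$test_ds)
  metrics <- ev$metrics
  results <- list(test = ev$fields)

  for (nm in names(cfg$extra_test_sets)) {
    extra <- cfg$extra_test_sets[[nm]]
    extra_ds <- encode_extra_test_set(data, extra)
    pred_x <- predict_ensemble(ensemble, extra_ds)
    ev_x <- evaluate_pair_predictions(pred_x, extra_ds, test_set = nm)
    metrics <- dplyr::bind_rows(metrics, ev_x$metrics)
    results[[nm]] <- ev_x$fields
  }

  structure(
    list(results = results, metrics = metrics, ensemble = ensemble,
         predictions = pred, data = data, config = cfg,
         manifest = c(data$manifest, list(
           n_splits = length(splits),
           splits = splits
         ))),
    class = "mtl_experiment"
  )
}

# Encode an additional held-out test corpus pair with the frozen
# vocabulary, sequence length and scalers of a prepared experiment.
encode_extra_test_set <- function(data, extra) {
  mt <- data$manifest$min_tokens
  docs_a <- preprocess_corpus(resolve_corpus(extra$corpus_a), mt)
  docs_b <- preprocess_corpus(resolve_corpus(extra$corpus_b), mt)
  docs_a$.y <- binary_labels(docs_a, data$task)
  docs_b$.y <- binary_labels(docs_b, "disorder")
  sel <- function(d) dplyr::select(d, "user_id", "tokens", "n_tokens",
                                   label = ".y")
  aligned <- align_tasks(sel(docs_a), sel(docs_b),
                         seed = data$manifest$seed + 302L)
  encode_pair(aligned, data$vocab, data$max_len, data$aux_ctx)
}

#' Run the single-task baselines of an experiment
#'
#' Trains the single-task convolutional baseline on the same stratified
#' splits for each task separately (no pairing, no soft-sharing term) and
#' reports the same metric vocabulary plus the majority-class baseline
#' accuracy of the test labels.
#'
#' @param cfg An [experiment_config()].
#' @param data Optional shared [prepare_experiment_data()] result.
#' @param tasks Which per-task baselines to train (default both).
#' @return An object of class `mtl_baselines`: per-task baseline metrics,
#'   ensembles, and majority-class accuracies.
#' @export
run_baselines <- function(cfg, data = NULL,
                          tasks = c("suicide", "disorder")) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (is.null(data)) data <- prepare_experiment_data(cfg)
  splits <- stratified_shuffle_splits(data$train_ds$y_a, cfg$split)

  task_ds <- list(
    suicide = mtl_dataset(x_a = data$train_ds$x_a, y_a = data$train_ds$y_a,
                          aux_a = data$train_ds$aux_a),
    disorder = mtl_dataset(x_a = data$train_ds$x_b,
                           y_a = data$train_ds$y_b,
                           aux_a = data$train_ds$aux_b)
  )
  test_ds <- list(
    suicide = mtl_dataset(x_a = data$test_ds$x_a, y_a = data$test_ds$y_a,
                          aux_a = data$test_ds$aux_a),
    disorder = mtl_dataset(x_a = data$test_ds$x_b, y_a = data$test_ds$y_b,
                           aux_a = data$test_ds$aux_b)
  )

  task_ds <- task_ds[tasks]
  test_ds <- test_ds[tasks]
  out <- purrr::imap(task_ds, function(ds, task) {
    ens <- train_ensemble(ds, splits, data$model_cfg, cfg$training,
                          kind = "single")
    pred <- predict_ensemble(ens, test_ds[[task]])
    m <- metrics_report(test_ds[[task]]$y_a, pred$labels[[1]],
                        pred$probs[[1]][, 2], task = task)
    list(ensemble = ens, metrics = m,
         majority_accuracy =
           majority_baseline_accuracy(test_ds[[task]]$y_a))
  })

  structure(
    list(
      metrics = purrr::map_dfr(out, "metrics"),
      majority = purrr::map_dbl(out, "majority_accuracy"),
      ensembles = purrr::map(out, "ensemble"),
      config = cfg
    ),
    class = "mtl_baselines"
  )
}

#' @export
print.mtl_experiment <- function(x, ...) {
  cat("<mtl_experiment>\n")
  print(x$metrics)
  invisible(x)
}

#' @export
print.mtl_baselines <- function(x, ...) {
  cat("<mtl_baselines>\n")
  print(x$metrics)
  cat("majority-class accuracy:",
      paste(sprintf("%s %.3f", names(x$majority), x$majority),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy metrics of an experiment
#' @param x An `mtl_experiment`.
#' @param ... Unused.
#' @return The metrics tibble (one row per test set and task).
#' @export
tidy.mtl_experiment <- function(x, ...) x$metrics

#' One-row summary of an experiment
#' @param x An `mtl_experiment`.
#' @param ... Unused.
#' @return A one-row tibble with the ten standard metric fields on the
#'   primary test set.
#' @export
glance.mtl_experiment <- function(x, ...) {
  tibble::as_tibble(x$results$test)
}

#' Write experiment results as JSON
#'
#' Emits the named metric fields (Ps ... AUCm) per test set plus the run
#' manifest (seeds, sizes, splits) for reproducibility.
#'
#' @param experiment An `mtl_experiment`.
#' @param path Output path.
#' @export
write_experiment_json <- function(experiment, path) {
  payload <- list(
    results = experiment$results,
    manifest = experiment$manifest[
      setdiff(names(experiment$manifest), "splits")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Plot experiment metrics
#'
#' @param object An `mtl_experiment`.
#' @param ... Unused.
#' @return A ggplot bar chart of the macro metrics per task and test set.
#' @export
autoplot.mtl_experiment <- function(object, ...) {
  long <- object$metrics |>
    tidyr::pivot_longer(c("macro_precision", "macro_recall", "macro_f1",
                          "accuracy", "macro_auc"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value,
                                     fill = .data$task)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~test_set) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Ensemble test metrics per task") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}
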