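test_that("early stopping fires after the patience window on a flat trace", {
  cfg <- train_config()
  sim <- simulate_protocol(rep(1.0, 10), cfg)
  expect_equal(attr(sim, "stopped_epoch"), 4L)
  expect_equal(attr(sim, "best_epoch"), 1L)
  expect_equal(nrow(sim), 4L)
})

test_that("learning rate decays by the plateau factor and respects the floor", {
  cfg <- train_config()
  # strictly improving: no decay, no stop
  sim <- simulate_protocol(seq(1, 0.1, length.out = 10), cfg)
  expect_true(all(sim$lr == 0.001))
  expect_true(is.na(attr(sim, "stopped_epoch")))
  expect_equal(attr(sim, "best_epoch"), 10L)

  # two consecutive non-improving epochs: 0.001 -> 0.0001 from epoch 4
  sim2 <- simulate_protocol(c(1, 1.1, 1.1, 0.9), cfg)
  expect_equal(sim2$lr, c(0.001, 0.001, 0.001, 0.0001))
  expect_equal(attr(sim2, "best_epoch"), 4L)

  # repeated plateaus drive the rate down to (but not below) min_lr
  long <- simulate_protocol(c(1, rep(1.5, 30)),
                            train_config(max_epochs = 40,
                                         early_stop_patience = 31))
  expect_gte(min(long$lr), 1e-8)
  expect_equal(min(long$lr), 1e-8)

  # improvements below min_delta do not reset the counters
  sim3 <- simulate_protocol(c(1, 1 - 1e-9, 1 - 2e-9, 1 - 3e-9),
                            train_config())
  expect_equal(attr(sim3, "stopped_epoch"), 4L)
})

test_that("training restores the weights of the best validation epoch", {
  cfg <- tiny_model_config(vocab_size = 40L, dropout_p = 0)
  gen <- tiny_generator_config(vocab_size = 40L, signal_rate = 0.6,
                               n_per_class = 12L, doc_length = 30,
                               min_tokens = 10L)
  pair <- generate_corpus_pair(gen)
  cc <- cleaning_config("synthetic", min_tokens = 1)
  docs_a <- build_user_documents(pair$corpus_a, cc)
  docs_b <- build_user_documents(pair$corpus_b, cc)
  tr_a <- docs_a[docs_a$split == "train", ]
  tr_b <- docs_b[docs_b$split == "train", ]
  vocab <- build_vocabulary(tr_a$tokens, tr_b$tokens, 60)
  ds <- mtl_dataset(
    x_a = encode_and_pad(tr_a$tokens, vocab, cfg$max_len),
    y_a = collapse_risk(tr_a$label, "flagged"),
    x_b = encode_and_pad(tr_b$tokens, vocab, cfg$max_len),
    y_b = collapse_risk(tr_b$label, "disorder")
  )
  split <- list(train = 1:18, val = 19:24)
  tcfg <- train_config(max_epochs = 6, seed = 3)
  net <- build_mtl_network(with_vocab_size(cfg, length(vocab) + 2L),
                           seed = 3)
  fit <- train_mtl(net, ds, split, tcfg)

  expect_equal(fit$best_epoch,
               which.min(fit$history$val_loss))
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  # the returned network evaluates to the best recorded validation loss
  vl <- mtlrisk:::validation_eval(fit$network, ds, split$val)
  expect_equal(vl$loss, fit$best_val_loss, tolerance = 1e-10)
  # batches are never reshuffled across epochs
  expect_length(unique(fit$history$batch_signature), 1)

  # determinism: same seeds, same history
  net2 <- build_mtl_network(with_vocab_size(cfg, length(vocab) + 2L),
                            seed = 3)
  fit2 <- train_mtl(net2, ds, split, tcfg)
  expect_equal(fit$history, fit2$history)
  expect_error(train_mtl(net2, ds, list(train = integer(0), val = 1:3),
                         tcfg), "nonempty")
})

test_that("training on separable synthetic data reduces validation loss", {
  for (seed in c(5, 6, 7)) {
    gen <- tiny_generator_config(signal_rate = 0.5, seed = seed,
                                 n_per_class = 25L)
    ecfg <- experiment_config(
      task = "flagged", generator = gen,
      model = list(embed_dim = 8, n_filters = 8, dense_units = 12),
      training = train_config(max_epochs = 6, seed = seed),
      split = split_spec(n_splits = 1, seed = seed),
      max_len = 40, seed = seed
    )
    data <- prepare_experiment_data(ecfg)
    split <- stratified_shuffle_splits(data$train_ds$y_a, ecfg$split)[[1]]
    net <- build_mtl_network(data$model_cfg, seed = seed)
    fit <- train_mtl(net, data$train_ds, split,
                     ecfg$training)
    expect_lt(fit$best_val_loss, fit$history$val_loss[1])
  }
})

test_that("single-task training follows the same stopping rules and learns", {
  gen <- tiny_generator_config(signal_rate = 0.7, seed = 9,
                               n_per_class = 40L, doc_length = 80)
  ecfg <- experiment_config(
    task = "flagged", generator = gen,
    model = list(embed_dim = 16, n_filters = 16, dense_units = 12),
    training = train_config(max_epochs = 10, seed = 9),
    split = split_spec(n_splits = 1, seed = 9),
    max_len = 60, seed = 9
  )
  data <- prepare_experiment_data(ecfg)
  split <- stratified_shuffle_splits(data$train_ds$y_a, ecfg$split)[[1]]
  net <- build_single_task_baseline(data$model_cfg, seed = 9)
  fit <- train_single_task(net, data$train_ds, split, ecfg$training)
  expect_s3_class(fit, "mtl_fit")
  expect_lte(fit$stopped_epoch, 10)
  # above-chance validation accuracy on separable data
  expect_gt(max(fit$history$val_acc_a), 0.5)
  expect_true(all(is.na(fit$history$val_cce_b)))
})

test_that("ensemble averaging behaves linearly and checks configs", {
  cfg <- tiny_model_config()
  nets <- lapply(1:3, function(s) build_mtl_network(cfg, seed = s))
  x1 <- random_index_batch(6, cfg$max_len, cfg$vocab_size, 1)
  x2 <- random_index_batch(6, cfg$max_len, cfg$vocab_size, 2)
  ds <- mtl_dataset(x_a = x1, y_a = rep(0L, 6), x_b = x2,
                    y_b = rep(0L, 6))
  pred <- predict_ensemble(nets, ds)
  # averaged probabilities equal the mean of the member outputs
  members <- lapply(nets, function(n) predict(n, x1, x2)$probs[[1]])
  expect_equal(pred$probs[[1]], Reduce(`+`, members) / 3)
  expect_equal(rowSums(pred$probs[[1]]), rep(1, 6), tolerance = 1e-12)
  expect_true(all(pred$probs[[1]] >= 0 & pred$probs[[1]] <= 1))
  # k copies of one model = that model
  same <- predict_ensemble(list(nets[[1]], nets[[1]]), ds)
  expect_equal(same$probs[[1]], members[[1]])
  # config mismatch errors
  other <- build_mtl_network(tiny_model_config(n_filters = 4L), seed = 1)
  expect_error(predict_ensemble(list(nets[[1]], other), ds),
               "differing model configurations")
})

test_that("ensembles are reproducible from the master seed", {
  gen <- tiny_generator_config(n_per_class = 15L, seed = 13)
  ecfg <- experiment_config(
    task = "flagged", generator = gen,
    model = list(embed_dim = 6, n_filters = 4, dense_units = 8),
    training = train_config(max_epochs = 2, seed = 13),
    split = split_spec(n_splits = 2, seed = 13),
    max_len = 30, seed = 13
  )
  data <- prepare_experiment_data(ecfg)
  splits <- stratified_shuffle_splits(data$train_ds$y_a, ecfg$split)
  e1 <- train_ensemble(data$train_ds, splits, data$model_cfg,
                       ecfg$training)
  e2 <- train_ensemble(data$train_ds, splits, data$model_cfg,
                       ecfg$training)
  expect_length(e1$fits, 2)
  expect_equal(lapply(e1$fits, function(f) f$network$params),
               lapply(e2$fits, function(f) f$network$params))
  # one split degenerates to a single model
  e3 <- train_ensemble(data$train_ds, splits[1], data$model_cfg,
                       ecfg$training)
  p3 <- predict_ensemble(e3, data$test_ds)
  p3m <- predict(e3$fits[[1]]$network, data$test_ds$x_a, data$test_ds$x_b)
  expect_equal(p3$probs[[1]], p3m$probs[[1]])
})
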