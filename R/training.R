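#' Training configuration
#'
#' The published optimisation protocol: Adam at learning rate 0.001,
#' mini-batches of 8 formed over pair rows in stored order (never
#' shuffled, to preserve positive-with-positive task alignment), at most
#' 10 epochs with early stopping after 3 epochs without validation-loss
#' improvement, learning rate multiplied by 0.1 after 2 non-improving
#' epochs with a floor of 1e-8, and the weights of the lowest
#' validation-loss epoch returned for inference.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Mini-batch size (8; 16 and 32 were the alternatives).
#' @param max_epochs Hard cap on epochs.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param lr_reduce_factor Multiplicative learning-rate decay on plateau.
#' @param lr_reduce_patience Non-improving epochs before a decay step.
#' @param min_lr Learning-rate floor.
#' @param min_delta Minimum decrease in validation loss that counts as an
#'   improvement for both patience counters.
#' @param seed Integer seed (dropout masks; ensemble member seeds derive
#'   from it deterministically).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001,
                         batch_size = 8L,
                         max_epochs = 10L,
                         early_stop_patience = 3L,
                         lr_reduce_factor = 0.1,
                         lr_reduce_patience = 2L,
                         min_lr = 1e-8,
                         min_delta = 1e-6,
                         seed = 1L) {
  stopifnot(
    learning_rate > 0, batch_size >= 1, max_epochs >= 1,
    early_stop_patience >= 1, lr_reduce_patience >= 1,
    lr_reduce_factor > 0, lr_reduce_factor < 1,
    min_lr < learning_rate, min_delta >= 0
  )
  structure(
    list(
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs),
      early_stop_patience = as.integer(early_stop_patience),
      lr_reduce_factor = lr_reduce_factor,
      lr_reduce_patience = as.integer(lr_reduce_patience),
      min_lr = min_lr,
      min_delta = min_delta,
      seed = as.integer(seed),
      shuffle = FALSE
    ),
    class = "train_config"
  )
}

new_protocol_state <- function(cfg) {
  list(epoch = 0L, best = Inf, best_epoch = 0L, wait_stop = 0L,
       wait_lr = 0L, lr = cfg$learning_rate, stop = FALSE)
}

# One protocol step: a pure function of (state, observed validation
# loss). Both patience counters track the same best-loss reference and
# run independently; the learning-rate counter resets after a decay.
protocol_update <- function(state, val_loss, cfg) {
  state$epoch <- state$epoch + 1L
  if (val_loss < state$best - cfg$min_delta) {
    state$best <- val_loss
    state$best_epoch <- state$epoch
    state$wait_stop <- 0L
    state$wait_lr <- 0L
  } else {
    state$wait_stop <- state$wait_stop + 1L
    state$wait_lr <- state$wait_lr + 1L
    if (state$wait_lr >= cfg$lr_reduce_patience) {
      state$lr <- max(state$lr * cfg$lr_reduce_factor, cfg$min_lr)
      state$wait_lr <- 0L
    }
    if (state$wait_stop >= cfg$early_stop_patience) state$stop <- TRUE
  }
  state
}

#' Apply the early-stopping and plateau rules to a scripted loss trace
#'
#' Pure protocol simulation: feeds a sequence of validation losses
#' through the early-stopping and learning-rate-plateau rules without
#' training anything. `lr` is the learning rate in force while the
#' epoch's batches were processed (decays take effect from the following
#' epoch).
#'
#' @param val_losses Numeric vector of validation losses per epoch.
#' @param cfg A [train_config()].
#' @return A tibble with columns `epoch`, `val_loss`, `lr`, `improved`;
#'   attributes `best_epoch` and `stopped_epoch` (`NA` if the trace ends
#'   before the stopping rule fires).
#' @export
simulate_protocol <- function(val_losses, cfg = train_config()) {
  st <- new_protocol_state(cfg)
  rows <- vector("list", length(val_losses))
  stopped <- NA_integer_
  for (e in seq_along(val_losses)) {
    lr_used <- st$lr
    prev_best <- st$best
    st <- protocol_update(st, val_losses[e], cfg)
    rows[[e]] <- tibble::tibble(
      epoch = e, val_loss = val_losses[e], lr = lr_used,
      improved = val_losses[e] < prev_best - cfg$min_delta
    )
    if (st$stop) {
      stopped <- e
      break
    }
  }
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  attr(out, "best_epoch") <- st$best_epoch
  attr(out, "stopped_epoch") <- stopped
  out
}

#' Assemble an encoded aligned dataset
#'
#' Packs the encoded sequences, labels and optional scaled auxiliary
#' features of an aligned pair dataset into the container the training
#' routines consume.
#'
#' @param x_a,x_b Integer index matrices (rows aligned across tasks).
#' @param y_a,y_b Binary label vectors; the pairing contract requires
#'   `y_a == y_b` row by row.
#' @param aux_a,aux_b Optional auxiliary feature matrices.
#' @param user_id_a,user_id_b Optional user identifiers.
#' @return An object of class `mtl_dataset`.
#' @export
mtl_dataset <- function(x_a, y_a, x_b = NULL, y_b = NULL, aux_a = NULL,
                        aux_b = NULL, user_id_a = NULL, user_id_b = NULL) {
  stopifnot(nrow(x_a) == length(y_a))
  if (!is.null(x_b)) {
    stopifnot(nrow(x_b) == nrow(x_a), length(y_b) == length(y_a))
    if (!all(y_a == y_b)) {
      stop("aligned rows must be label-homogeneous (y_a == y_b)",
           call. = FALSE)
    }
  }
  structure(
    list(x_a = x_a, y_a = as.integer(y_a), x_b = x_b,
         y_b = if (is.null(y_b)) NULL else as.integer(y_b),
         aux_a = aux_a, aux_b = aux_b,
         user_id_a = user_id_a, user_id_b = user_id_b,
         n = nrow(x_a)),
    class = "mtl_dataset"
  )
}

subset_dataset <- function(ds, idx) {
  sub <- function(m) if (is.null(m)) NULL else m[idx, , drop = FALSE]
  mtl_dataset(
    x_a = ds$x_a[idx, , drop = FALSE], y_a = ds$y_a[idx],
    x_b = sub(ds$x_b), y_b = if (is.null(ds$y_b)) NULL else ds$y_b[idx],
    aux_a = sub(ds$aux_a), aux_b = sub(ds$aux_b),
    user_id_a = ds$user_id_a[idx], user_id_b = ds$user_id_b[idx]
  )
}

batch_order_signature <- function(n, batch_size) {
  starts <- seq(1L, n, by = batch_size)
  paste(n, batch_size, paste(starts, collapse = ","), sep = "|")
}

validation_eval <- function(network, ds, idx) {
  val <- subset_dataset(ds, idx)
  if (network$n_tasks == 2) {
    out <- predict(network, val$x_a, val$x_b, aux = val$aux_a,
                   aux2 = val$aux_b)
    loss <- mtl_loss(val$y_a, out$probs[[1]], val$y_b, out$probs[[2]],
                     out$task_vecs[[1]], out$task_vecs[[2]],
                     lambda = network$config$soft_share_weight)
    list(loss = loss$total, cce_a = loss$cce_suicide,
         cce_b = loss$cce_disorder, mse = loss$soft_share_mse,
         acc_a = mean((out$probs[[1]][, 2] > 0.5) == (val$y_a == 1)),
         acc_b = mean((out$probs[[2]][, 2] > 0.5) == (val$y_b == 1)))
  } else {
    out <- predict(network, val$x_a, aux = val$aux_a)
    p <- out$probs[[1]]
    cce <- mean(-log(clip_probs(p[cbind(seq_along(val$y_a),
                                        val$y_a + 1L)])))
    list(loss = cce, cce_a = cce, cce_b = NA_real_, mse = NA_real_,
         acc_a = mean((p[, 2] > 0.5) == (val$y_a == 1)),
         acc_b = NA_real_)
  }
}

train_network <- function(network, ds, split, cfg) {
  stopifnot(inherits(ds, "mtl_dataset"), inherits(cfg, "train_config"))
  if (length(split$train) == 0 || length(split$val) == 0) {
    stop("train and validation splits must both be nonempty",
         call. = FALSE)
  }
  train <- subset_dataset(ds, split$train)
  ccfg <- cpp_config(network$config, network$n_tasks, network$use_dense)
  X <- list(train$x_a)
  Y <- list(train$y_a)
  AUX <- vector("list", network$n_tasks)
  AUX[1] <- list(train$aux_a)
  if (network$n_tasks == 2) {
    X[[2]] <- train$x_b
    Y[[2]] <- train$y_b
    AUX[2] <- list(train$aux_b)
  }

  params <- network$params
  adam_m <- list()
  adam_v <- list()
  adam_t <- 0L
  st <- new_protocol_state(cfg)
  best_params <- params
  sig <- batch_order_signature(train$n, cfg$batch_size)
  history <- list()

  for (epoch in seq_len(cfg$max_epochs)) {
    lr_used <- st$lr
    drop_seed <- (as.numeric(cfg$seed) * 131071 + epoch * 8191) %%
      2147483647
    ep <- cpp_train_epoch(params, adam_m, adam_v, adam_t, ccfg, X, Y,
                          AUX, lr_used, cfg$batch_size,
                          as.integer(drop_seed))
    params <- ep$params
    adam_m <- ep$adam_m
    adam_v <- ep$adam_v
    adam_t <- ep$adam_t

    net_now <- network
    net_now$params <- params
    vl <- validation_eval(net_now, ds, split$val)
    prev_best <- st$best
    st <- protocol_update(st, vl$loss, cfg)
    if (vl$loss < prev_best - cfg$min_delta) best_params <- params

    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_loss = ep$train_loss_data,
      train_reg = ep$train_loss_reg,
      train_soft_share_mse = ep$train_soft_share_mse,
      val_loss = vl$loss,
      val_cce_a = vl$cce_a, val_cce_b = vl$cce_b,
      val_soft_share_mse = vl$mse,
      val_acc_a = vl$acc_a, val_acc_b = vl$acc_b,
      lr = lr_used,
      batch_signature = sig
    )
    if (st$stop) break
  }

  network$params <- best_params
  structure(
    list(
      network = network,
      history = dplyr::bind_rows(history),
      best_epoch = st$best_epoch,
      stopped_epoch = st$epoch,
      best_val_loss = st$best,
      train_config = cfg,
      split = split
    ),
    class = "mtl_fit"
  )
}

#' Train the multi-task network on one split
#'
#' Runs the full protocol of [train_config()] on an aligned encoded
#' dataset: batches are formed over pair rows in stored order (no
#' shuffling), the summed loss (two cross-entropies plus the weighted
#' soft-sharing penalty, plus L1/L2 weight decay) is minimised with Adam,
#' validation loss drives the plateau and early-stopping rules, and the
#' weights of the best validation epoch are restored.
#'
#' @param network An [build_mtl_network()] network.
#' @param ds An [mtl_dataset()] with both tasks present.
#' @param split A list with integer index vectors `train` and `val`.
#' @param cfg A [train_config()].
#' @return An object of class `mtl_fit` (trained network + history).
#' @export
train_mtl <- function(network, ds, split, cfg = train_config()) {
  stopifnot(network$n_tasks == 2, !is.null(ds$x_b))
  train_network(network, ds, split, cfg)
}

#' Train the single-task baseline on one split
#'
#' Same protocol as [train_mtl()] without pairing or the soft-sharing
#' term: plain categorical cross-entropy on one task's rows.
#'
#' @param network A [build_single_task_baseline()] network.
#' @param ds An [mtl_dataset()]; only the task-A slots are used.
#' @param split A list with `train` and `val` index vectors.
#' @param cfg A [train_config()].
#' @return An `mtl_fit`.
#' @export
train_single_task <- function(network, ds, split, cfg = train_config()) {
  stopifnot(network$n_tasks == 1)
  ds1 <- mtl_dataset(x_a = ds$x_a, y_a = ds$y_a, aux_a = ds$aux_a,
                     user_id_a = ds$user_id_a)
  train_network(network, ds1, split, cfg)
}

#' Train one model per stratified split (the ensemble)
#'
#' Each split gets an independently initialised network whose seed is
#' derived deterministically from `cfg$seed`, trained under the shared
#' protocol; inference averages the member probabilities.
#'
#' @param ds An [mtl_dataset()].
#' @param splits A list of splits from [stratified_shuffle_splits()].
#' @param model_cfg An [model_config()].
#' @param cfg A [train_config()].
#' @param kind `"mtl"` or `"single"`.
#' @return An object of class `mtl_ensemble` (list of `mtl_fit`s).
#' @export
train_ensemble <- function(ds, splits, model_cfg, cfg = train_config(),
                           kind = c("mtl", "single")) {
  kind <- match.arg(kind)
  stopifnot(length(splits) >= 1)
  fits <- purrr::imap(splits, function(split, i) {
    seed_i <- as.integer((as.numeric(cfg$seed) * 977 + i * 104729) %%
                           2147483647)
    net <- if (kind == "mtl") build_mtl_network(model_cfg, seed = seed_i)
           else build_single_task_baseline(model_cfg, seed = seed_i)
    cfg_i <- cfg
    cfg_i$seed <- seed_i
    train_network(net, ds, split, cfg_i)
  })
  structure(list(fits = fits, kind = kind, model_config = model_cfg,
                 train_config = cfg),
            class = "mtl_ensemble")
}

#' Model-averaging ensemble inference
#'
#' Averages the predicted class probabilities of all member models
#' elementwise (rows still sum to 1), then takes the per-row argmax.
#'
#' @param ensemble An [train_ensemble()] result (or a list of `mtl_fit`
#'   / `mtl_network` objects sharing one configuration).
#' @param ds An [mtl_dataset()] with the rows to predict.
#' @return A list with `probs` (per-task averaged probability matrices)
#'   and `labels` (per-task argmax label vectors).
#' @export
predict_ensemble <- function(ensemble, ds) {
  nets <- if (inherits(ensemble, "mtl_ensemble")) {
    lapply(ensemble$fits, `[[`, "network")
  } else {
    lapply(ensemble, function(f) {
      if (inherits(f, "mtl_fit")) f$network else f
    })
  }
  stopifnot(length(nets) >= 1)
  cfg0 <- nets[[1]]$config
  for (nt in nets) {
    if (!identical(nt$config, cfg0)) {
      stop("ensemble members have differing model configurations",
           call. = FALSE)
    }
  }
  n_tasks <- nets[[1]]$n_tasks
  acc <- NULL
  for (nt in nets) {
    out <- if (n_tasks == 2) {
      predict(nt, ds$x_a, ds$x_b, aux = ds$aux_a, aux2 = ds$aux_b)
    } else {
      predict(nt, ds$x_a, aux = ds$aux_a)
    }
    if (is.null(acc)) {
      acc <- out$probs
    } else {
      for (t in seq_len(n_tasks)) acc[[t]] <- acc[[t]] + out$probs[[t]]
    }
  }
  probs <- lapply(acc, function(p) p / length(nets))
  labels <- lapply(probs, function(p) max.col(p, ties.method = "first") - 1L)
  list(probs = probs, labels = labels)
}

#' @export
print.mtl_fit <- function(x, ...) {
  cat(sprintf(
    "<mtl_fit: %s, stopped epoch %d, best epoch %d (val loss %.4f)>\n",
    x$network$kind, x$stopped_epoch, x$best_epoch, x$best_val_loss
  ))
  invisible(x)
}

#' @export
print.mtl_ensemble <- function(x, ...) {
  cat(sprintf("<mtl_ensemble: %d %s model(s)>\n", length(x$fits), x$kind))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fit
#' @param x An `mtl_fit`.
#' @param ... Unused.
#' @return The history tibble (one row per epoch).
#' @export
tidy.mtl_fit <- function(x, ...) x$history

#' One-row summary of a fit
#' @param x An `mtl_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mtl_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$network$kind,
    epochs_run = x$stopped_epoch,
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    final_lr = x$history$lr[nrow(x$history)],
    n_parameters = n_parameters(x$network)
  )
}

#' Member summaries of an ensemble
#' @param x An `mtl_ensemble`.
#' @param ... Unused.
#' @return A tibble with one row per member model.
#' @export
tidy.mtl_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, i) {
    dplyr::bind_cols(tibble::tibble(model = i), glance(f))
  })
}

#' Plot training curves of a fit
#'
#' @param object An `mtl_fit`.
#' @param ... Unused.
#' @return A ggplot object: train and validation loss per epoch, with
#'   the best (restored) epoch marked.
#' @export
autoplot.mtl_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
                        names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_epoch,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = h$epoch) +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = "Training history",
                  subtitle = "dashed line: restored best epoch") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
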