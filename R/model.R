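#' Model configuration for the multi-task convolutional network
#'
#' Collects every architectural hyperparameter of the dual-branch
#' multi-channel CNN. The defaults reproduce the published configuration:
#' trainable 300-dimensional randomly initialised embeddings, two
#' convolution channels per task with kernel sizes 3 and 4 and 256 filters
#' each, global max pooling, dropout 0.5, a 512-unit fully connected layer
#' per channel, L1/L2 weight decay of 1e-5 on convolution and dense
#' kernels, and a shared representation of width
#' `2 * n_channels * dense_units` (2,048) read by two softmax heads.
#'
#' @param vocab_size Number of embedding rows, including the reserved
#'   padding (0) and out-of-vocabulary (1) indices.
#' @param max_len Uniform encoded sequence length.
#' @param embed_dim Embedding dimension (default 300).
#' @param n_channels Number of convolution channels per task branch.
#' @param kernel_sizes Integer vector of kernel widths, one per channel.
#' @param n_filters Convolution filters per channel.
#' @param dense_units Hidden units of the per-channel dense layer present
#'   in the multi-task branches (the single-task baseline has none).
#' @param dropout_p Dropout probability applied to the pooled convolution
#'   outputs, in `[0, 1)`.
#' @param l1_factor,l2_factor Weight-decay factors applied to convolution
#'   and fully connected kernels (not embeddings, biases, or heads).
#' @param activation `"relu"` or `"leaky_relu"`.
#' @param leaky_alpha Negative-slope coefficient when `activation` is
#'   `"leaky_relu"`.
#' @param aux_units Width of the auxiliary dense layer fusing lexicon
#'   category scores into each task vector, or `NULL` for no auxiliary
#'   input. Published settings are 8, 16 or 32 depending on the task.
#' @param aux_dim Number of lexicon categories in the auxiliary feature
#'   vector (required when `aux_units` is set).
#' @param n_classes Classes per softmax head (binary tasks: 2).
#' @param soft_share_weight Weight of the soft-sharing mean-squared-error
#'   term in the joint loss. The published loss sums the terms, i.e. 1.
#'
#' @return An object of class `mtl_model_config` (a validated list).
#' @export
model_config <- function(vocab_size,
                         max_len,
                         embed_dim = 300L,
                         n_channels = 2L,
                         kernel_sizes = c(3L, 4L),
                         n_filters = 256L,
                         dense_units = 512L,
                         dropout_p = 0.5,
                         l1_factor = 1e-5,
                         l2_factor = 1e-5,
                         activation = c("relu", "leaky_relu"),
                         leaky_alpha = 0.2,
                         aux_units = NULL,
                         aux_dim = NULL,
                         n_classes = 2L,
                         soft_share_weight = 1) {
  activation <- match.arg(activation)
  stopifnot(
    vocab_size >= 2, max_len >= 1, embed_dim >= 1,
    n_channels >= 1, length(kernel_sizes) == n_channels,
    all(kernel_sizes >= 1), n_filters >= 1, dense_units >= 1,
    dropout_p >= 0, dropout_p < 1,
    l1_factor >= 0, l2_factor >= 0,
    n_classes >= 2, soft_share_weight >= 0
  )
  if (max_len < max(kernel_sizes)) {
    stop("max_len (", max_len, ") must be >= the largest kernel size (",
         max(kernel_sizes), ")", call. = FALSE)
  }
  if (!is.null(aux_units)) {
    stopifnot(aux_units >= 1)
    if (is.null(aux_dim) || aux_dim < 1) {
      stop("aux_dim (number of lexicon categories) is required when ",
           "aux_units is set", call. = FALSE)
    }
  }
  structure(
    list(
      vocab_size = as.integer(vocab_size),
      max_len = as.integer(max_len),
      embed_dim = as.integer(embed_dim),
      n_channels = as.integer(n_channels),
      kernel_sizes = as.integer(kernel_sizes),
      n_filters = as.integer(n_filters),
      dense_units = as.integer(dense_units),
      dropout_p = dropout_p,
      l1_factor = l1_factor,
      l2_factor = l2_factor,
      activation = activation,
      leaky_alpha = leaky_alpha,
      aux_units = if (is.null(aux_units)) 0L else as.integer(aux_units),
      aux_dim = if (is.null(aux_dim)) 0L else as.integer(aux_dim),
      n_classes = as.integer(n_classes),
      soft_share_weight = soft_share_weight
    ),
    class = "mtl_model_config"
  )
}

# Internal: config list handed to the compiled kernels.
cpp_config <- function(config, n_tasks, use_dense) {
  list(
    n_tasks = as.integer(n_tasks),
    max_len = config$max_len,
    embed_dim = config$embed_dim,
    n_filters = config$n_filters,
    dense_units = config$dense_units,
    use_dense = use_dense,
    kernel_sizes = config$kernel_sizes,
    act = if (config$activation == "relu") 0L else 1L,
    leaky_alpha = config$leaky_alpha,
    dropout_p = config$dropout_p,
    l1_factor = config$l1_factor,
    l2_factor = config$l2_factor,
    soft_share_weight = config$soft_share_weight,
    aux_units = config$aux_units,
    aux_dim = config$aux_dim,
    n_classes = config$n_classes
  )
}

#' Width of one task representation vector implied by a configuration
#'
#' For the multi-task branches this is
#' `n_channels * dense_units + aux_units` (1,024 at defaults, 1,032 with an
#' 8-unit auxiliary branch); the shared representation concatenates two such
#' vectors.
#'
#' @param config An [model_config()] object.
#' @param use_dense Whether the branch contains the per-channel dense layer
#'   (`TRUE` for multi-task branches, `FALSE` for the single-task baseline).
#' @return Integer width.
#' @export
task_vector_width <- function(config, use_dense = TRUE) {
  per_chan <- if (use_dense) config$dense_units else config$n_filters
  config$n_channels * per_chan + config$aux_units
}

glorot_uniform <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_params <- function(config, n_tasks, use_dense, seed, tie_branches = FALSE) {
  withr::with_seed(seed, {
    p <- list()
    shared_w <- n_tasks * task_vector_width(config, use_dense)
    for (t in seq_len(n_tasks)) {
      p[[paste0("embed_", t)]] <-
        matrix(runif(config$vocab_size * config$embed_dim, -0.05, 0.05),
               config$vocab_size, config$embed_dim)
      for (ch in seq_len(config$n_channels)) {
        k <- config$kernel_sizes[ch]
        p[[paste0("conv_W_", t, "_", ch)]] <-
          glorot_uniform(k * config$embed_dim, config$n_filters)
        p[[paste0("conv_b_", t, "_", ch)]] <-
          matrix(0, 1, config$n_filters)
        if (use_dense) {
          p[[paste0("dense_W_", t, "_", ch)]] <-
            glorot_uniform(config$n_filters, config$dense_units)
          p[[paste0("dense_b_", t, "_", ch)]] <-
            matrix(0, 1, config$dense_units)
        }
      }
      if (config$aux_units > 0) {
        p[[paste0("aux_W_", t)]] <-
          glorot_uniform(config$aux_dim, config$aux_units)
        p[[paste0("aux_b_", t)]] <- matrix(0, 1, config$aux_units)
      }
    }
    for (t in seq_len(n_tasks)) {
      p[[paste0("head_W_", t)]] <- glorot_uniform(shared_w, config$n_classes)
      p[[paste0("head_b_", t)]] <- matrix(0, 1, config$n_classes)
    }
    if (tie_branches && n_tasks == 2) {
      # Copy branch 1 weights into branch 2 so that identical aligned
      # inputs give identical task vectors (soft-share MSE of zero).
      branch1 <- "^(embed|conv_W|conv_b|dense_W|dense_b|aux_W|aux_b)_1"
      for (nm in grep(branch1, names(p), value = TRUE)) {
        nm2 <- sub(branch1, "\\1_2", nm)
        if (nm2 %in% names(p)) p[[nm2]] <- p[[nm]]
      }
    }
    p
  })
}

#' Build the dual-branch multi-task network
#'
#' Constructs two structurally identical task branches with independent
#' weights (suicide-ideation branch and mental-disorder branch), a shared
#' representation formed by concatenating the two task vectors, and one
#' softmax head per task, both reading the full shared representation.
#'
#' @param config An [model_config()] object.
#' @param seed Integer seed for the weight initialisation (embeddings
#'   uniform on \eqn{[-0.05, 0.05]}, kernels Glorot-uniform, biases zero).
#' @param tie_branches If `TRUE`, branch 2 is initialised with copies of
#'   branch 1's weights; with identical aligned inputs the soft-sharing
#'   distance is then exactly zero at step 0. Used for diagnostics.
#' @return An object of class `mtl_network`.
#' @export
build_mtl_network <- function(config, seed = 1L, tie_branches = FALSE) {
  stopifnot(inherits(config, "mtl_model_config"))
  structure(
    list(
      params = init_params(config, 2L, TRUE, seed, tie_branches),
      config = config,
      kind = "mtl",
      use_dense = TRUE,
      n_tasks = 2L,
      seed = as.integer(seed)
    ),
    class = "mtl_network"
  )
}

#' Build the single-task convolutional baseline
#'
#' One embedding, the same two convolution channels (kernels 3 and 4, 256
#' filters), global max pooling and dropout; the pooled channel outputs are
#' concatenated and fed directly to a single softmax head. Trained with
#' plain categorical cross-entropy (no soft-sharing term).
#'
#' @inheritParams build_mtl_network
#' @return An object of class `mtl_network` with `kind = "single"`.
#' @export
build_single_task_baseline <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mtl_model_config"))
  structure(
    list(
      params = init_params(config, 1L, FALSE, seed),
      config = config,
      kind = "single",
      use_dense = FALSE,
      n_tasks = 1L,
      seed = as.integer(seed)
    ),
    class = "mtl_network"
  )
}

#' @export
print.mtl_network <- function(x, ...) {
  cat(sprintf(
    "<mtl_network: %s, %d task(s), %s parameters>\n",
    x$kind, x$n_tasks, format(n_parameters(x), big.mark = ",")
  ))
  print(network_summary(x), n = Inf)
  invisible(x)
}

#' Total number of trainable parameters of a network
#'
#' @param network An `mtl_network`.
#' @return Integer count.
#' @export
n_parameters <- function(network) {
  sum(vapply(network$params, length, integer(1)))
}

#' Layer-by-layer output widths of a network
#'
#' Used for the structural assertions on the architecture: at published
#' defaults the multi-task shared representation is 2,048 wide, and with an
#' 8-unit auxiliary branch each regularised task vector is 1,032 wide.
#'
#' @param network An `mtl_network`.
#' @return A tibble with columns `layer` and `width`.
#' @export
network_summary <- function(network) {
  cfg <- network$config
  per_chan <- if (network$use_dense) cfg$dense_units else cfg$n_filters
  tv <- task_vector_width(cfg, network$use_dense)
  rows <- list(
    tibble::tibble(layer = "embedding", width = cfg$embed_dim),
    tibble::tibble(
      layer = paste0("conv_k", cfg$kernel_sizes, "_pooled"),
      width = cfg$n_filters
    )
  )
  if (network$use_dense) {
    rows <- c(rows, list(tibble::tibble(
      layer = paste0("dense_ch", seq_len(cfg$n_channels)),
      width = cfg$dense_units
    )))
  }
  if (cfg$aux_units > 0) {
    rows <- c(rows, list(tibble::tibble(layer = "aux_dense",
                                        width = cfg$aux_units)))
  }
  rows <- c(rows, list(
    tibble::tibble(layer = "task_vector", width = tv),
    tibble::tibble(layer = "shared_representation",
                   width = network$n_tasks * tv),
    tibble::tibble(
      layer = paste0("softmax_head_", seq_len(network$n_tasks)),
      width = cfg$n_classes
    )
  ))
  dplyr::bind_rows(rows)
}

as_index_matrix <- function(x, max_len) {
  if (is.vector(x)) x <- matrix(as.integer(x), nrow = 1)
  storage.mode(x) <- "integer"
  if (ncol(x) != max_len) {
    stop("encoded input has ", ncol(x), " columns; expected max_len = ",
         max_len, call. = FALSE)
  }
  x
}

#' Forward pass of a network
#'
#' Dropout is disabled unless `training = TRUE`, so repeated inference on
#' the same input is bit-identical.
#'
#' @param object An `mtl_network`.
#' @param x Encoded integer matrix (rows = users, `max_len` columns) for
#'   the first (suicide-ideation) task.
#' @param x2 Encoded matrix for the second (mental-disorder) task; required
#'   for multi-task networks, ignored for the baseline.
#' @param aux,aux2 Optional scaled auxiliary feature matrices, one row per
#'   user, when the network was configured with `aux_units`.
#' @param training Apply dropout (training mode) if `TRUE`.
#' @param dropout_seed Integer seed for the dropout masks in training mode.
#' @param ... Unused.
#' @return A list with `probs` (per-task probability matrices, rows sum to
#'   1) and `task_vecs` (per-task representation vectors).
#' @export
predict.mtl_network <- function(object, x, x2 = NULL, aux = NULL,
                                aux2 = NULL, training = FALSE,
                                dropout_seed = 0L, ...) {
  cfg <- object$config
  X <- list(as_index_matrix(x, cfg$max_len))
  AUX <- vector("list", object$n_tasks)
  AUX[1] <- list(aux)
  if (object$n_tasks == 2) {
    if (is.null(x2)) {
      stop("multi-task network needs both task inputs (x and x2)",
           call. = FALSE)
    }
    X[[2]] <- as_index_matrix(x2, cfg$max_len)
    AUX[2] <- list(aux2)
  }
  if (cfg$aux_units > 0 && is.null(aux)) {
    stop("network was built with an auxiliary branch; supply aux features",
         call. = FALSE)
  }
  out <- cpp_forward(object$params, cpp_config(cfg, object$n_tasks,
                                               object$use_dense),
                     X, AUX, training, as.integer(dropout_seed))
  out
}

clip_probs <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1)

as_onehot <- function(y, n_classes = 2L) {
  if (is.matrix(y)) return(y)
  y <- as.integer(y)
  out <- matrix(0, length(y), n_classes)
  out[cbind(seq_along(y), y + 1L)] <- 1
  out
}

#' Joint multi-task loss
#'
#' The summed objective: categorical cross-entropy for each task (mean over
#' the batch, probabilities clipped at 1e-7 before the log) plus
#' `lambda` times the soft-sharing penalty, the mean over the batch of the
#' mean squared elementwise difference between the two task representation
#' vectors of each aligned pair.
#'
#' @param y_s,y_m True labels per task: binary vectors (0/1) or one-hot
#'   matrices.
#' @param p_s,p_m Predicted probability matrices (rows sum to 1).
#' @param v_s,v_m Task representation matrices of equal width, row-aligned.
#' @param lambda Weight of the soft-sharing term (default 1: the terms are
#'   summed).
#' @return A list of class `mtl_loss` with components `total`,
#'   `cce_suicide`, `cce_disorder`, `soft_share_mse`.
#' @export
#' @examples
#' p <- matrix(c(0.5, 0.5), 1)
#' v <- matrix(0, 1, 4)
#' mtl_loss(0, p, 0, p, v, v)$total  # 2 * ln 2
mtl_loss <- function(y_s, p_s, y_m, p_m, v_s, v_m, lambda = 1) {
  if (!all(dim(v_s) == dim(v_m))) {
    stop("task vectors have mismatched shapes: ",
         paste(dim(v_s), collapse = "x"), " vs ",
         paste(dim(v_m), collapse = "x"), call. = FALSE)
  }
  Y_s <- as_onehot(y_s, ncol(p_s))
  Y_m <- as_onehot(y_m, ncol(p_m))
  cce <- function(Y, P) mean(-rowSums(Y * log(clip_probs(P))))
  cce_s <- cce(Y_s, p_s)
  cce_m <- cce(Y_m, p_m)
  mse <- mean(rowMeans((v_s - v_m)^2))
  structure(
    list(
      total = cce_s + cce_m + lambda * mse,
      cce_suicide = cce_s,
      cce_disorder = cce_m,
      soft_share_mse = mse,
      lambda = lambda
    ),
    class = "mtl_loss"
  )
}

#' @export
print.mtl_loss <- function(x, ...) {
  cat(sprintf(
    "mtl loss: total %.6f (cce_s %.6f + cce_m %.6f + %g * mse %.6f)\n",
    x$total, x$cce_suicide, x$cce_disorder, x$lambda, x$soft_share_mse
  ))
  invisible(x)
}

# Internal: analytic gradients for one batch (exposed for the
# finite-difference verification in the test suite).
network_gradients <- function(network, x, y, x2 = NULL, y2 = NULL,
                              aux = NULL, aux2 = NULL, training = FALSE,
                              dropout_seed = 0L) {
  cfg <- network$config
  X <- list(as_index_matrix(x, cfg$max_len))
  Y <- list(as.integer(y))
  AUX <- vector("list", network$n_tasks)
  AUX[1] <- list(aux)
  if (network$n_tasks == 2) {
    X[[2]] <- as_index_matrix(x2, cfg$max_len)
    Y[[2]] <- as.integer(y2)
    AUX[2] <- list(aux2)
  }
  cpp_loss_and_grads(network$params,
                     cpp_config(cfg, network$n_tasks, network$use_dense),
                     X, Y, AUX, training, as.integer(dropout_seed), TRUE)
}

network_loss <- function(network, x, y, x2 = NULL, y2 = NULL, aux = NULL,
                         aux2 = NULL, training = FALSE, dropout_seed = 0L) {
  cfg <- network$config
  X <- list(as_index_matrix(x, cfg$max_len))
  Y <- list(as.integer(y))
  AUX <- vector("list", network$n_tasks)
  AUX[1] <- list(aux)
  if (network$n_tasks == 2) {
    X[[2]] <- as_index_matrix(x2, cfg$max_len)
    Y[[2]] <- as.integer(y2)
    AUX[2] <- list(aux2)
  }
  cpp_loss_and_grads(network$params,
                     cpp_config(cfg, network$n_tasks, network$use_dense),
                     X, Y, AUX, training, as.integer(dropout_seed), FALSE)
}
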