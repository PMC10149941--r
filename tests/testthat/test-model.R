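test_that("architecture widths match the published configuration", {
  cfg <- model_config(vocab_size = 50, max_len = 20)
  expect_equal(task_vector_width(cfg), 1024L)
  net <- build_mtl_network(cfg, seed = 1)
  sm <- network_summary(net)
  expect_equal(sm$width[sm$layer == "shared_representation"], 2048L)

  cfg8 <- model_config(vocab_size = 50, max_len = 20, aux_units = 8,
                       aux_dim = 14)
  expect_equal(task_vector_width(cfg8), 1032L)

  cfg1 <- model_config(vocab_size = 50, max_len = 20, n_channels = 1,
                       kernel_sizes = 3L)
  expect_equal(task_vector_width(cfg1), 512L)

  expect_error(model_config(vocab_size = 50, max_len = 3,
                            kernel_sizes = c(3L, 4L)), "kernel size")
  expect_error(model_config(vocab_size = 50, max_len = 20, aux_units = 8),
               "aux_dim")
})

test_that("forward pass emits row-normalised probabilities of the right shape", {
  cfg <- tiny_model_config()
  net <- build_mtl_network(cfg, seed = 2)
  x1 <- random_index_batch(5, cfg$max_len, cfg$vocab_size, 1)
  x2 <- random_index_batch(5, cfg$max_len, cfg$vocab_size, 2)
  out <- predict(net, x1, x2)
  for (t in 1:2) {
    expect_equal(dim(out$probs[[t]]), c(5L, 2L))
    expect_equal(rowSums(out$probs[[t]]), rep(1, 5), tolerance = 1e-12)
    expect_true(all(out$probs[[t]] >= 0))
    expect_equal(ncol(out$task_vecs[[t]]), task_vector_width(cfg))
  }
  expect_equal(ncol(out$shared), 2 * task_vector_width(cfg))
  # inference is deterministic (dropout off)
  expect_identical(out, predict(net, x1, x2))
})

test_that("tied-branch initialisation gives zero soft-share distance", {
  cfg <- tiny_model_config()
  net <- build_mtl_network(cfg, seed = 3, tie_branches = TRUE)
  x <- random_index_batch(4, cfg$max_len, cfg$vocab_size, 9)
  out <- predict(net, x, x)
  expect_equal(out$task_vecs[[1]], out$task_vecs[[2]])
  loss <- mtl_loss(rep(0L, 4), out$probs[[1]], rep(0L, 4), out$probs[[2]],
                   out$task_vecs[[1]], out$task_vecs[[2]])
  expect_equal(loss$soft_share_mse, 0)
})

test_that("joint loss reproduces its closed forms", {
  # perfect one-hot predictions and identical vectors: zero loss
  p_perfect <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  v <- matrix(0, 2, 4)
  l0 <- mtl_loss(c(0L, 1L), p_perfect, c(0L, 1L), p_perfect, v, v)
  expect_equal(l0$total, 0, tolerance = 1e-6)

  # uniform predictions on both tasks: 2 ln 2
  p_half <- matrix(0.5, 1, 2)
  l1 <- mtl_loss(0L, p_half, 0L, p_half, matrix(0, 1, 2), matrix(0, 1, 2))
  expect_equal(l1$total, 2 * log(2), tolerance = 1e-9)

  # orthogonal unit vectors with perfect predictions: MSE (1+1)/2 = 1
  l2 <- mtl_loss(0L, matrix(c(1, 0), 1), 0L, matrix(c(1, 0), 1),
                 matrix(c(1, 0), 1), matrix(c(0, 1), 1), lambda = 1)
  expect_equal(l2$total, 1, tolerance = 1e-9)
  expect_equal(l2$soft_share_mse, 1)

  # additivity invariant
  expect_equal(l1$total,
               l1$cce_suicide + l1$cce_disorder + 1 * l1$soft_share_mse)
  expect_error(mtl_loss(0L, p_half, 0L, p_half, matrix(0, 1, 2),
                        matrix(0, 1, 3)), "mismatched shapes")
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(vocab_size = 20, max_len = 8, embed_dim = 4,
                      n_filters = 3, dense_units = 5,
                      kernel_sizes = c(2L, 3L), dropout_p = 0,
                      l1_factor = 0, l2_factor = 2e-3, aux_units = 3,
                      aux_dim = 2, soft_share_weight = 0.7,
                      activation = "leaky_relu")
  net <- build_mtl_network(cfg, seed = 42)
  withr::with_seed(7, {
    x1 <- matrix(sample(0:19, 24, TRUE), 3)
    x2 <- matrix(sample(0:19, 24, TRUE), 3)
    a1 <- matrix(runif(6), 3)
    a2 <- matrix(runif(6), 3)
  })
  y1 <- c(0L, 1L, 0L)
  y2 <- c(0L, 1L, 1L)
  g <- mtlrisk:::network_gradients(net, x1, y1, x2, y2, a1, a2)
  eps <- 1e-6
  withr::with_seed(1, {
    for (nm in names(net$params)) {
      P <- net$params[[nm]]
      for (i in sample(length(P), min(4, length(P)))) {
        np <- net
        np$params[[nm]][i] <- P[i] + eps
        fp <- mtlrisk:::network_loss(np, x1, y1, x2, y2, a1,
                                     a2)$loss_total
        np$params[[nm]][i] <- P[i] - eps
        fm <- mtlrisk:::network_loss(np, x1, y1, x2, y2, a1,
                                     a2)$loss_total
        num <- (fp - fm) / (2 * eps)
        ana <- g$grads[[nm]][i]
        expect_equal(ana, num, tolerance = 1e-4,
                     info = paste(nm, i))
      }
    }
  })
})

test_that("every trainable tensor receives gradient for generic inputs", {
  cfg <- tiny_model_config(aux_units = 3L, aux_dim = 2L,
                           l2_factor = 1e-5)
  net <- build_mtl_network(cfg, seed = 5)
  withr::with_seed(3, {
    x1 <- random_index_batch(6, cfg$max_len, cfg$vocab_size, 31)
    x2 <- random_index_batch(6, cfg$max_len, cfg$vocab_size, 32)
    a1 <- matrix(runif(12), 6)
    a2 <- matrix(runif(12), 6)
  })
  g <- mtlrisk:::network_gradients(net, x1, c(0L, 1L, 0L, 1L, 0L, 1L),
                                   x2, c(1L, 0L, 1L, 0L, 1L, 0L), a1, a2)
  norms <- vapply(g$grads, function(m) sqrt(sum(m^2)), numeric(1))
  expect_true(all(norms > 0), info = paste(names(norms)[norms == 0],
                                           collapse = ", "))
})

test_that("loss is invariant under joint permutation of pair rows", {
  cfg <- tiny_model_config()
  net <- build_mtl_network(cfg, seed = 8)
  x1 <- random_index_batch(6, cfg$max_len, cfg$vocab_size, 41)
  x2 <- random_index_batch(6, cfg$max_len, cfg$vocab_size, 42)
  y1 <- c(0L, 1L, 1L, 0L, 1L, 0L)
  y2 <- y1
  base <- mtlrisk:::network_loss(net, x1, y1, x2, y2)$loss_total
  withr::with_seed(11, {
    for (i in 1:5) {
      p <- sample(6)
      perm <- mtlrisk:::network_loss(net, x1[p, ], y1[p], x2[p, ],
                                     y2[p])$loss_total
      expect_equal(perm, base, tolerance = 1e-12)
    }
  })
})

test_that("single-task baseline is smaller and feeds one softmax head", {
  cfg <- tiny_model_config()
  mtl <- build_mtl_network(cfg, seed = 1)
  stl <- build_single_task_baseline(cfg, seed = 1)
  expect_lt(n_parameters(stl), n_parameters(mtl))
  x <- random_index_batch(4, cfg$max_len, cfg$vocab_size, 5)
  out <- predict(stl, x)
  expect_length(out$probs, 1)
  expect_equal(rowSums(out$probs[[1]]), rep(1, 4), tolerance = 1e-12)
  # baseline task vector is the concatenated pooled channels (no dense)
  expect_equal(ncol(out$task_vecs[[1]]),
               cfg$n_channels * cfg$n_filters)
  # same seed, same input: deterministic outputs
  stl2 <- build_single_task_baseline(cfg, seed = 1)
  expect_identical(predict(stl2, x), out)
})

test_that("dropout is active in training mode only and is seeded", {
  cfg <- tiny_model_config(dropout_p = 0.5)
  net <- build_mtl_network(cfg, seed = 4)
  x1 <- random_index_batch(4, cfg$max_len, cfg$vocab_size, 21)
  x2 <- random_index_batch(4, cfg$max_len, cfg$vocab_size, 22)
  inf1 <- predict(net, x1, x2)
  inf2 <- predict(net, x1, x2)
  expect_identical(inf1, inf2)
  tr1 <- predict(net, x1, x2, training = TRUE, dropout_seed = 7)
  tr2 <- predict(net, x1, x2, training = TRUE, dropout_seed = 7)
  tr3 <- predict(net, x1, x2, training = TRUE, dropout_seed = 8)
  expect_identical(tr1, tr2)
  expect_false(identical(tr1, tr3))
})
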