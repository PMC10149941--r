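# Shared fixtures: tiny configurations and generated corpora used across
# the module tests. Everything is built in code under fixed seeds.

tiny_model_config <- function(...) {
  defaults <- list(
    vocab_size = 30L, max_len = 12L, embed_dim = 4L,
    kernel_sizes = c(2L, 3L), n_filters = 3L, dense_units = 5L,
    dropout_p = 0, l1_factor = 0, l2_factor = 0
  )
  do.call(model_config, modifyList(defaults, list(...)))
}

tiny_generator_config <- function(...) {
  defaults <- list(
    vocab_size = 120L, n_categories = 6L, terms_per_category = 5L,
    n_signal_categories = 2L, signal_rate = 0.3, cross_task_overlap = 1,
    doc_length = 60, min_tokens = 20L, n_per_class = 20L,
    n_test_pos = 10L, n_test_neg = 5L, seed = 7L
  )
  do.call(generator_config, modifyList(defaults, list(...)))
}

random_index_batch <- function(n, max_len, vocab_size, seed = 1) {
  withr::with_seed(seed, {
    matrix(sample(0:(vocab_size - 1), n * max_len, replace = TRUE),
           n, max_len)
  })
}

make_doc_tibble <- function(n, prefix = "u", label = "none") {
  tibble::tibble(
    user_id = paste0(prefix, seq_len(n)),
    tokens = replicate(n, c("a", "b"), simplify = FALSE),
    n_tokens = 2L,
    label = label
  )
}

with_vocab_size <- function(cfg, vocab_size) {
  cfg$vocab_size <- as.integer(vocab_size)
  cfg
}
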