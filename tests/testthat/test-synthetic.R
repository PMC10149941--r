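test_that("generated lexicon categories are disjoint and overlap obeys rho", {
  for (seed in c(1, 2, 3)) {
    gl <- generate_lexicon(tiny_generator_config(seed = seed))
    cats <- gl$lexicon$categories
    all_terms <- unlist(cats)
    expect_false(any(duplicated(all_terms)))
    expect_true(all(lengths(cats) == 5))
  }
  m <- 5L * 2L  # terms_per_category * n_signal_categories
  gl1 <- generate_lexicon(tiny_generator_config(cross_task_overlap = 1))
  expect_setequal(gl1$manifest$signal_terms_a, gl1$manifest$signal_terms_b)
  gl0 <- generate_lexicon(tiny_generator_config(cross_task_overlap = 0))
  expect_length(intersect(gl0$manifest$signal_terms_a,
                          gl0$manifest$signal_terms_b), 0)
  gl_half <- generate_lexicon(
    tiny_generator_config(cross_task_overlap = 0.5))
  expect_length(gl_half$manifest$shared_terms, round(0.5 * m))
  expect_error(generate_lexicon(
    tiny_generator_config(n_categories = 4L, terms_per_category = 40L)))
})

test_that("corpora are byte-identical under one seed and differ across seeds", {
  cfg <- tiny_generator_config(seed = 17)
  p1 <- generate_corpus_pair(cfg)
  p2 <- generate_corpus_pair(cfg)
  expect_identical(p1$corpus_a, p2$corpus_a)
  expect_identical(p1$corpus_b, p2$corpus_b)
  p3 <- generate_corpus_pair(tiny_generator_config(seed = 18))
  expect_false(identical(p1$corpus_a, p3$corpus_a))
})

test_that("generated corpora have the configured structure and survive filtering", {
  cfg <- tiny_generator_config(seed = 4)
  pair <- generate_corpus_pair(cfg)
  docs <- build_user_documents(pair$corpus_a,
                               cleaning_config("synthetic",
                                               min_tokens = cfg$min_tokens))
  # every generated user passes the minimum-token filter by construction
  expect_equal(nrow(filter_min_tokens(docs, cfg$min_tokens)), nrow(docs))
  # class and split counts
  tr <- docs[docs$split == "train", ]
  te <- docs[docs$split == "test", ]
  expect_equal(sum(collapse_risk(tr$label, "flagged")), cfg$n_per_class)
  expect_equal(sum(1 - collapse_risk(tr$label, "flagged")),
               cfg$n_per_class)
  expect_equal(sum(collapse_risk(te$label, "flagged")), cfg$n_test_pos)
  expect_equal(sum(1 - collapse_risk(te$label, "flagged")),
               cfg$n_test_neg)
  # task-A positives carry the printed risk-level proportions
  big <- generate_corpus_pair(tiny_generator_config(n_per_class = 369L,
                                                    seed = 5))
  lab <- dplyr::distinct(big$corpus_a[c("user_id", "label", "split")])
  tr_lab <- table(lab$label[lab$split == "train"])
  expect_equal(as.integer(tr_lab[c("low", "moderate", "severe")]),
               c(50L, 113L, 206L))
  # posts per user stay in the configured range
  ppu <- table(pair$corpus_a$user_id)
  expect_true(all(ppu >= 1 & ppu <= cfg$posts_per_user[2]))
})

test_that("signal-term frequency in positive documents matches the mixture", {
  cfg <- tiny_generator_config(vocab_size = 200L, signal_rate = 0.4,
                               doc_length = 150, n_per_class = 40L,
                               seed = 21, background = "uniform")
  pair <- generate_corpus_pair(cfg)
  man <- pair$manifest
  docs <- build_user_documents(pair$corpus_a,
                               cleaning_config("synthetic", min_tokens = 1))
  pos <- docs[collapse_risk(docs$label, "flagged") == 1 &
                docs$split == "train", ]
  neg <- docs[collapse_risk(docs$label, "flagged") == 0 &
                docs$split == "train", ]
  frac_signal <- function(d) {
    toks <- unlist(d$tokens)
    mean(toks %in% man$signal_terms_a)
  }
  bg_mass <- length(man$signal_terms_a) / cfg$vocab_size
  expected_pos <- cfg$signal_rate + (1 - cfg$signal_rate) * bg_mass
  n_pos_tokens <- sum(pos$n_tokens)
  se <- sqrt(expected_pos * (1 - expected_pos) / n_pos_tokens)
  expect_lt(abs(frac_signal(pos) - expected_pos), 3 * se)
  se_neg <- sqrt(bg_mass * (1 - bg_mass) / sum(neg$n_tokens))
  expect_lt(abs(frac_signal(neg) - bg_mass), 3 * se_neg)
})

test_that("pi = 0 makes the classes indistinguishable (chance AUC)", {
  aucs <- vapply(c(31, 32, 33), function(seed) {
    cfg <- tiny_generator_config(signal_rate = 0, n_per_class = 40L,
                                 n_test_pos = 40L, n_test_neg = 40L,
                                 doc_length = 40, seed = seed)
    pair <- generate_corpus_pair(cfg)
    man <- pair$manifest
    docs <- build_user_documents(pair$corpus_a,
                                 cleaning_config("synthetic",
                                                 min_tokens = 1))
    te <- docs[docs$split == "test", ]
    # a signal-count score: optimal for pi > 0, uninformative at pi = 0
    score <- vapply(te$tokens,
                    function(t) mean(t %in% man$signal_terms_a),
                    numeric(1))
    macro_auc(collapse_risk(te$label, "flagged"), score)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("Monte-Carlo category scores match the closed-form expectations", {
  cfg <- tiny_generator_config(vocab_size = 150L, signal_rate = 0.35,
                               doc_length = 120, n_per_class = 60L,
                               seed = 41, background = "uniform")
  expct <- expected_aux_signal(cfg)
  # closed form under a uniform background: m / V for controls and
  # pi / K_signal + (1 - pi) * m / V for signal categories
  m <- cfg$terms_per_category
  expect_equal(expct$expected_control, rep(m / cfg$vocab_size,
                                           cfg$n_categories))
  sig_cats <- paste0("category_0", seq_len(cfg$n_signal_categories))
  expect_equal(
    expct$expected_positive_a[expct$category %in% sig_cats],
    rep(cfg$signal_rate / cfg$n_signal_categories +
          (1 - cfg$signal_rate) * m / cfg$vocab_size,
        cfg$n_signal_categories)
  )

  pair <- generate_corpus_pair(cfg)
  docs <- build_user_documents(pair$corpus_a,
                               cleaning_config("synthetic", min_tokens = 1))
  feats <- score_categories(docs, pair$lexicon)
  pos <- collapse_risk(docs$label, "flagged") == 1
  for (cn in expct$category) {
    mc_pos <- mean(feats[[cn]][pos])
    mc_neg <- mean(feats[[cn]][!pos])
    want_pos <- expct$expected_positive_a[expct$category == cn]
    want_neg <- expct$expected_control[expct$category == cn]
    se_pos <- stats::sd(feats[[cn]][pos]) / sqrt(sum(pos))
    se_neg <- stats::sd(feats[[cn]][!pos]) / sqrt(sum(!pos))
    expect_lt(abs(mc_pos - want_pos), 3 * se_pos + 1e-9)
    expect_lt(abs(mc_neg - want_neg), 3 * se_neg + 1e-9)
  }
})

test_that("zipf background probabilities are a proper skewed distribution", {
  cfg <- tiny_generator_config(background = "zipf", zipf_s = 1.1)
  man <- generate_lexicon(cfg)$manifest
  p <- man$background_probs
  expect_equal(sum(p), 1)
  expect_true(all(diff(p) <= 0))
  expect_gt(p[1] / p[length(p)], 10)
})
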