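test_that("risk collapsing matches the task positive sets", {
  expect_equal(collapse_risk("low", "flagged"), 1L)
  expect_equal(collapse_risk("low", "urgent"), 0L)
  expect_equal(collapse_risk("none", "flagged"), 0L)
  expect_equal(collapse_risk("control", "urgent"), 0L)
  expect_equal(collapse_risk(c("moderate", "severe"), "urgent"), c(1L, 1L))
  expect_equal(collapse_risk("disorder", "disorder"), 1L)
  expect_error(collapse_risk("bogus", "flagged"), "unknown risk label")
  # the urgent positive set is strictly contained in the flagged one
  expect_true(all(task_spec("urgent")$positive_set %in%
                    task_spec("flagged")$positive_set))
  expect_gt(length(task_spec("flagged")$positive_set),
            length(task_spec("urgent")$positive_set))
})

test_that("published class distribution reproduces the corpus-assembly totals", {
  dist <- umd_class_distribution()
  train <- dist[dist$split == "train", ]
  for (tk in c("flagged", "urgent")) {
    tr <- train[train$task == tk, ]
    risk_rows <- tr[tr$class_label %in% risk_levels(), ]
    pos_total <- sum(risk_rows$n[collapse_risk(risk_rows$class_label, tk)
                                 == 1])
    neg_total <- sum(risk_rows$n[collapse_risk(risk_rows$class_label, tk)
                                 == 0])
    topup <- tr$n[tr$class_label == "random_control"]
    expect_equal(pos_total, if (tk == "flagged") 369L else 319L)
    expect_equal(topup, pos_total - neg_total)
    expect_equal(sum(tr$n), if (tk == "flagged") 738L else 638L)
  }
  # the full-corpus crowdsource counts are consistent with train + test
  ann <- umd_annotator_counts()
  cs <- setNames(ann$n[ann$annotator == "crowdsource"],
                 ann$class_label[ann$annotator == "crowdsource"])
  tt <- dist[dist$task == "flagged" & dist$split %in% c("train", "test") &
               dist$class_label %in% risk_levels(), ]
  for (lv in c("none", "low", "moderate", "severe")) {
    expect_equal(sum(tt$n[tt$class_label == lv]), unname(cs[lv]))
  }
})

test_that("control balancing equalises classes and errors on a short pool", {
  pos <- make_doc_tibble(369, "p", "low")
  neg <- make_doc_tibble(127, "n", "none")
  pool <- make_doc_tibble(621, "c", "control")
  out <- balance_with_controls(pos, neg, pool, seed = 3)
  expect_equal(length(out$sampled_ids), 242L)
  expect_equal(nrow(out$dataset), 738L)
  expect_equal(sum(out$dataset$label == 1), sum(out$dataset$label == 0))
  expect_false(any(duplicated(out$sampled_ids)))
  # deterministic under a fixed seed
  out2 <- balance_with_controls(pos, neg, pool, seed = 3)
  expect_identical(out$sampled_ids, out2$sampled_ids)
  expect_false(identical(
    out$sampled_ids,
    balance_with_controls(pos, neg, pool, seed = 4)$sampled_ids
  ))
  # already balanced: nothing sampled
  out3 <- balance_with_controls(pos, make_doc_tibble(369, "n"), pool)
  expect_length(out3$sampled_ids, 0)
  expect_error(
    balance_with_controls(pos, neg, make_doc_tibble(100, "c")),
    "100 users but 242 are needed"
  )
  expect_error(
    balance_with_controls(make_doc_tibble(2, "p"), make_doc_tibble(3, "n"),
                          pool),
    "at least as many positives"
  )
})

test_that("task alignment pairs positives with positives", {
  a <- make_doc_tibble(7, "a")
  a$label <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L)
  b <- make_doc_tibble(7, "b")
  b$label <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L)
  al <- align_tasks(a, b, seed = 5)
  expect_equal(nrow(al), 7L)
  lab_a <- a$label[match(al$user_id_a, a$user_id)]
  lab_b <- b$label[match(al$user_id_b, b$user_id)]
  expect_equal(lab_a, lab_b)
  expect_equal(al$label, lab_a)
  # determinism and a complete pairing
  expect_identical(align_tasks(a, b, seed = 5), al)
  expect_setequal(al$user_id_b, b$user_id)
  # mismatched class counts fail loudly
  b_bad <- b[-4, ]
  expect_error(align_tasks(a, b_bad, seed = 1), "class counts differ")
})

test_that("stratified shuffle splits preserve class ratios within one row", {
  labels <- rep(c(1L, 0L), each = 5)
  splits <- stratified_shuffle_splits(labels, split_spec(5, 0.8, seed = 2))
  expect_length(splits, 5)
  for (sp in splits) {
    expect_length(sp$train, 8)
    expect_length(sp$val, 2)
    expect_equal(sum(labels[sp$train]), 4)
    expect_equal(sum(labels[sp$val]), 1)
    expect_length(intersect(sp$train, sp$val), 0)
    expect_setequal(c(sp$train, sp$val), seq_along(labels))
  }
  expect_identical(splits,
                   stratified_shuffle_splits(labels,
                                             split_spec(5, 0.8, seed = 2)))

  # ratio preservation across random shapes
  withr::with_seed(11, {
    for (i in 1:100) {
      n1 <- sample(5:40, 1)
      n0 <- sample(5:40, 1)
      lab <- sample(rep(c(1L, 0L), c(n1, n0)))
      frac <- runif(1, 0.5, 0.9)
      sp <- stratified_shuffle_splits(lab, split_spec(1, frac, 99))[[1]]
      for (part in sp) {
        expected_pos <- length(part) * n1 / (n1 + n0)
        expect_lte(abs(sum(lab[part]) - expected_pos), 1)
      }
    }
  })
  expect_error(stratified_shuffle_splits(rep(1L, 4), split_spec()),
               "both classes")
  expect_error(
    stratified_shuffle_splits(c(1L, rep(0L, 9)), split_spec(1, 0.5)),
    "too few rows"
  )
})

test_that("vocabulary ranks by pooled frequency with lexicographic ties", {
  v <- build_vocabulary(list(c("a", "a", "b")), list(c("b", "c")),
                        max_size = 4)
  expect_equal(unname(v[c("a", "b")]), c(2L, 3L))
  expect_false("c" %in% names(v))
  # higher pooled frequency outranks lexicographic order
  v2 <- build_vocabulary(list(c("z", "z", "z", "a")), NULL, max_size = 10)
  expect_equal(unname(v2["z"]), 2L)
  expect_equal(unname(v2["a"]), 3L)
  expect_length(build_vocabulary(list(character(0)), NULL, 10), 0)
  expect_error(build_vocabulary(list("a"), NULL, max_size = 2), "at least 3")
})

test_that("encoding pads, truncates from the head, and round-trips", {
  v <- build_vocabulary(list(c("a", "a", "b", "c", "d")), NULL, 10)
  expect_equal(encode_and_pad(c("a", "b"), v, 4),
               c(v[["a"]], v[["b"]], 0L, 0L))
  long <- c("a", "b", "c", "d", "a", "b")
  expect_equal(encode_and_pad(long, v, 4),
               unname(v[long[1:4]]))
  expect_equal(encode_and_pad(long, v, 4, truncate = "tail"),
               unname(v[long[3:6]]))
  expect_equal(encode_and_pad("unseen", v, 3), c(1L, 0L, 0L))
  m <- encode_and_pad(list(c("a", "b"), "c"), v, 5)
  expect_equal(dim(m), c(2L, 5L))
  # every output row has exactly max_len entries; decode restores prefix
  withr::with_seed(3, {
    for (i in 1:20) {
      toks <- sample(c(names(v), "oovword"), sample(1:12, 1),
                     replace = TRUE)
      enc <- encode_and_pad(toks, v, 6)
      expect_length(enc, 6)
      dec <- decode_sequence(enc, v)
      keep <- head(toks, 6)
      expect_equal(dec[keep %in% names(v)][seq_len(sum(head(keep, 6) %in%
                                                         names(v)))],
                   keep[keep %in% names(v)])
    }
  })
})
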