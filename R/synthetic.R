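#' Configuration of the paired-corpus simulator
#'
#' The simulator emulates the statistical structure the multi-task
#' experiments assume: two user-level corpora (suicide-ideation side and
#' mental-disorder side) whose positive classes share a controllable
#' fraction of signal vocabulary. Each document is a bag of tokens drawn
#' independently from a mixture: with probability `signal_rate` (positives
#' only) from a uniform distribution over that task's signal terms,
#' otherwise from a fixed background distribution over the whole
#' vocabulary (Zipf by default, for a realistic frequency skew).
#'
#' Defaults mirror the published corpus dimensions: 369 users per class
#' per task for training, a 93/32 positive/negative test split, documents
#' of mean length 400 truncated below at the 50-token filter threshold,
#' and 4-level risk labels assigned to task-A positives in the printed
#' train (50:113:206) and test (13:28:52) low:moderate:severe proportions.
#'
#' @param vocab_size Vocabulary size V (default 3000).
#' @param n_categories Number of lexicon categories K (default 14).
#' @param terms_per_category Terms per category m (default 20).
#' @param n_signal_categories Categories forming each task's signal set
#'   (default 4; `2 * n_signal_categories <= n_categories` so fully
#'   disjoint signal sets are possible).
#' @param signal_rate Probability pi that a token of a positive document
#'   is drawn from the task's signal distribution; in `[0, 1)`.
#' @param cross_task_overlap Fraction rho of signal terms shared between
#'   the two tasks' positive classes; in `[0, 1]`.
#' @param doc_length Poisson mean document length (truncated below at
#'   `min_tokens`, so every generated user survives the token filter).
#' @param min_tokens Lower truncation for document lengths.
#' @param n_per_class Training users per class per task (default 369).
#' @param n_test_pos,n_test_neg Test users (default 93 positive, 32
#'   negative, the printed imbalanced test distribution).
#' @param posts_per_user Inclusive range of posts a user's document is
#'   split into.
#' @param background `"zipf"` (exponent `zipf_s`) or `"uniform"`.
#' @param zipf_s Zipf exponent of the background distribution.
#' @param seed Integer seed; the same seed reproduces the corpora
#'   byte-for-byte.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(vocab_size = 3000L,
                             n_categories = 14L,
                             terms_per_category = 20L,
                             n_signal_categories = 4L,
                             signal_rate = 0.3,
                             cross_task_overlap = 1,
                             doc_length = 400,
                             min_tokens = 50L,
                             n_per_class = 369L,
                             n_test_pos = 93L,
                             n_test_neg = 32L,
                             posts_per_user = c(3L, 10L),
                             background = c("zipf", "uniform"),
                             zipf_s = 1.1,
                             seed = 1L) {
  background <- match.arg(background)
  stopifnot(
    vocab_size >= 2,
    n_categories * terms_per_category <= vocab_size,
    2 * n_signal_categories <= n_categories,
    signal_rate >= 0, signal_rate < 1,
    cross_task_overlap >= 0, cross_task_overlap <= 1,
    doc_length > 0, min_tokens >= 1,
    n_per_class >= 1, n_test_pos >= 1, n_test_neg >= 1,
    length(posts_per_user) == 2, posts_per_user[1] >= 1,
    posts_per_user[2] >= posts_per_user[1]
  )
  structure(
    list(
      vocab_size = as.integer(vocab_size),
      n_categories = as.integer(n_categories),
      terms_per_category = as.integer(terms_per_category),
      n_signal_categories = as.integer(n_signal_categories),
      signal_rate = signal_rate,
      cross_task_overlap = cross_task_overlap,
      doc_length = doc_length,
      min_tokens = as.integer(min_tokens),
      n_per_class = as.integer(n_per_class),
      n_test_pos = as.integer(n_test_pos),
      n_test_neg = as.integer(n_test_neg),
      posts_per_user = as.integer(posts_per_user),
      background = background,
      zipf_s = zipf_s,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Purely alphabetic synthetic tokens ("q" + base-26 suffix) so that
# cleaning and stopword removal leave generated documents untouched.
synthetic_tokens <- function(n) {
  width <- max(1L, ceiling(log(n, 26)))
  idx <- seq_len(n) - 1L
  suffix <- vapply(idx, function(i) {
    chars <- character(width)
    for (p in width:1) {
      chars[p] <- letters[i %% 26 + 1L]
      i <- i %/% 26
    }
    paste(chars, collapse = "")
  }, character(1))
  paste0("q", suffix)
}

background_probs <- function(cfg) {
  if (cfg$background == "uniform") {
    rep(1 / cfg$vocab_size, cfg$vocab_size)
  } else {
    w <- (seq_len(cfg$vocab_size))^(-cfg$zipf_s)
    w / sum(w)
  }
}

# Printed risk-level proportions among task-A positives.
RISK_TRAIN_PROPS <- c(low = 50, moderate = 113, severe = 206)
RISK_TEST_PROPS <- c(low = 13, moderate = 28, severe = 52)

split_counts <- function(n, props) {
  exact <- n * props / sum(props)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate the synthetic lexicon and its ground-truth manifest
#'
#' Samples `n_categories` pairwise-disjoint categories of
#' `terms_per_category` terms each, without replacement from the
#' vocabulary. The first `n_signal_categories` categories form task A's
#' signal set; task B's signal set shares `round(rho * m * K_signal)`
#' terms with it and takes the remainder from the next block of
#' categories, so `rho = 1` gives identical signal sets and `rho = 0`
#' disjoint ones.
#'
#' @param cfg A [generator_config()].
#' @return A list with `lexicon` (an [lexicon()]) and `manifest`
#'   (signal-term sets, shared set, background probabilities, config).
#' @export
generate_lexicon <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  vocab <- synthetic_tokens(cfg$vocab_size)
  withr::with_seed(cfg$seed, {
    chosen <- sample(vocab, cfg$n_categories * cfg$terms_per_category)
  })
  cats <- split(chosen, rep(seq_len(cfg$n_categories),
                            each = cfg$terms_per_category))
  names(cats) <- sprintf("category_%02d", seq_len(cfg$n_categories))

  ks <- cfg$n_signal_categories
  signal_a <- unlist(cats[seq_len(ks)], use.names = FALSE)
  reserve <- unlist(cats[ks + seq_len(ks)], use.names = FALSE)
  n_shared <- round(cfg$cross_task_overlap * length(signal_a))
  signal_b <- c(head(signal_a, n_shared),
                head(reserve, length(signal_a) - n_shared))

  manifest <- list(
    config = cfg,
    vocabulary = vocab,
    background_probs = background_probs(cfg),
    categories = cats,
    signal_categories_a = names(cats)[seq_len(ks)],
    signal_terms_a = signal_a,
    signal_terms_b = signal_b,
    shared_terms = intersect(signal_a, signal_b)
  )
  list(lexicon = lexicon(cats, name = "synthetic"), manifest = manifest)
}

draw_document <- function(n_tokens, positive, signal_terms, vocab, bg_p,
                          signal_rate) {
  if (positive && signal_rate > 0) {
    from_signal <- runif(n_tokens) < signal_rate
    out <- character(n_tokens)
    n_sig <- sum(from_signal)
    if (n_sig > 0) {
      out[from_signal] <- sample(signal_terms, n_sig, replace = TRUE)
    }
    if (n_sig < n_tokens) {
      out[!from_signal] <- sample(vocab, n_tokens - n_sig, replace = TRUE,
                                  prob = bg_p)
    }
    out
  } else {
    sample(vocab, n_tokens, replace = TRUE, prob = bg_p)
  }
}

make_task_corpus <- function(cfg, manifest, task, prefix) {
  signal_terms <- if (task == "a") manifest$signal_terms_a
                  else manifest$signal_terms_b
  plan <- dplyr::bind_rows(
    tibble::tibble(split = "train", positive = TRUE,
                   n = cfg$n_per_class),
    tibble::tibble(split = "train", positive = FALSE,
                   n = cfg$n_per_class),
    tibble::tibble(split = "test", positive = TRUE, n = cfg$n_test_pos),
    tibble::tibble(split = "test", positive = FALSE, n = cfg$n_test_neg)
  )
  users <- list()
  u <- 0L
  for (r in seq_len(nrow(plan))) {
    n_users <- plan$n[r]
    positive <- plan$positive[r]
    # risk labels: task A positives carry the printed 4-level proportions
    labels <- if (task == "a") {
      if (positive) {
        props <- if (plan$split[r] == "train") RISK_TRAIN_PROPS
                 else RISK_TEST_PROPS
        rep(names(props), split_counts(n_users, props))
      } else {
        rep("control", n_users)
      }
    } else {
      rep(if (positive) "disorder" else "control", n_users)
    }
    for (i in seq_len(n_users)) {
      u <- u + 1L
      n_tok <- max(cfg$min_tokens, rpois(1, cfg$doc_length))
      toks <- draw_document(n_tok, positive, signal_terms,
                            manifest$vocabulary,
                            manifest$background_probs, cfg$signal_rate)
      n_posts <- sample(seq(cfg$posts_per_user[1], cfg$posts_per_user[2]),
                        1)
      n_posts <- min(n_posts, n_tok)
      bounds <- sort(c(0, sample(seq_len(n_tok - 1),
                                 min(n_posts - 1, n_tok - 1)), n_tok))
      texts <- vapply(seq_len(length(bounds) - 1), function(p) {
        paste(toks[(bounds[p] + 1):bounds[p + 1]], collapse = " ")
      }, character(1))
      users[[u]] <- tibble::tibble(
        user_id = sprintf("%s%05d", prefix, u),
        platform = "synthetic",
        label = labels[i],
        split = plan$split[r],
        t = seq_along(texts) * 3600,
        text = texts
      )
    }
  }
  dplyr::bind_rows(users)
}

#' Generate a paired two-task synthetic corpus
#'
#' Produces one corpus per task (suicide-ideation side with 4-level risk
#' labels, disorder side with disorder/control labels) as post-level
#' tibbles ready for [build_user_documents()], plus the ground-truth
#' manifest. Token distributions are class-conditional mixtures; the
#' fraction of signal vocabulary shared between the two tasks' positive
#' classes is `cross_task_overlap`. The same seed reproduces the output
#' exactly.
#'
#' @param cfg A [generator_config()].
#' @return A list with `corpus_a`, `corpus_b` (post-level tibbles:
#'   `user_id`, `platform`, `label`, `split`, `t`, `text`), `lexicon`,
#'   and `manifest`.
#' @export
generate_corpus_pair <- function(cfg) {
  gl <- generate_lexicon(cfg)
  corpora <- withr::with_seed(cfg$seed + 1L, {
    list(
      corpus_a = make_task_corpus(cfg, gl$manifest, "a", "ua"),
      corpus_b = make_task_corpus(cfg, gl$manifest, "b", "ub")
    )
  })
  c(corpora, list(lexicon = gl$lexicon, manifest = gl$manifest))
}

#' Closed-form expected category scores under the generator
#'
#' For a control document the expected normalised score of a category is
#' its background probability mass. For a positive document of task t it
#' is `pi * |c intersect S_t| / |S_t| + (1 - pi) * bg_mass(c)`, the
#' mixture of the uniform signal draw and the background draw. Used to
#' validate lexicon scoring on generated data.
#'
#' @param cfg A [generator_config()].
#' @return A tibble: `category`, `expected_control`,
#'   `expected_positive_a`, `expected_positive_b`.
#' @export
expected_aux_signal <- function(cfg) {
  gl <- generate_lexicon(cfg)
  man <- gl$manifest
  bg <- setNames(man$background_probs, man$vocabulary)
  pi_ <- cfg$signal_rate
  purrr::map_dfr(names(man$categories), function(cn) {
    terms <- man$categories[[cn]]
    bg_mass <- sum(bg[terms])
    sig_a <- length(intersect(terms, man$signal_terms_a)) /
      length(man$signal_terms_a)
    sig_b <- length(intersect(terms, man$signal_terms_b)) /
      length(man$signal_terms_b)
    tibble::tibble(
      category = cn,
      expected_control = bg_mass,
      expected_positive_a = pi_ * sig_a + (1 - pi_) * bg_mass,
      expected_positive_b = pi_ * sig_b + (1 - pi_) * bg_mass
    )
  })
}
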