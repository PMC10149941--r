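#' The 4-level suicide-risk taxonomy (plus the control group)
#' @return Character vector of the five label values.
#' @export
risk_levels <- function() c("none", "low", "moderate", "severe", "control")

#' Binary task specification
#'
#' The two suicide-ideation screening tasks collapse the 4-level risk
#' taxonomy differently: `flagged` (any risk) puts low, moderate and
#' severe in the positive class; `urgent` (needs urgent attention) puts
#' moderate and severe in the positive class. The `disorder` task is
#' already binary: its positive class is the `"disorder"` label.
#'
#' @param name `"flagged"`, `"urgent"` or `"disorder"`.
#' @return An object of class `binary_task_spec`.
#' @export
task_spec <- function(name = c("flagged", "urgent", "disorder")) {
  name <- match.arg(name)
  positive_set <- switch(name,
    flagged = c("low", "moderate", "severe"),
    urgent = c("moderate", "severe"),
    disorder = "disorder"
  )
  structure(list(name = name, positive_set = positive_set),
            class = "binary_task_spec")
}

#' Collapse risk labels to a binary class
#'
#' @param label Character vector of risk labels (values of
#'   [risk_levels()], or `"disorder"`/`"control"` for the disorder task).
#' @param task A [task_spec()] or a task name.
#' @return Integer vector: 1 for the positive class, 0 otherwise.
#' @export
#' @examples
#' collapse_risk(c("low", "none"), "flagged")  # 1 0
#' collapse_risk("low", "urgent")              # 0
collapse_risk <- function(label, task) {
  if (is.character(task)) task <- task_spec(task)
  valid <- c(risk_levels(), "disorder")
  bad <- setdiff(unique(label), valid)
  if (length(bad) > 0) {
    stop("unknown risk label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  as.integer(label %in% task$positive_set)
}

#' Balance a task dataset by sampling control users
#'
#' Tops up the negative class with users sampled uniformly without
#' replacement from a control pool until the class counts are equal,
#' mirroring the published corpus assembly (e.g. 242 random controls for
#' the flagged task, 142 for the urgent task).
#'
#' @param positives,negatives Tibbles of user documents (any columns; a
#'   `user_id` column is required).
#' @param control_pool Tibble of candidate control users, disjoint from
#'   `negatives`.
#' @param seed Integer seed for the sampling.
#' @return A list with `dataset` (positives then negatives then sampled
#'   controls, with a `label` column: 1 positive, 0 negative) and
#'   `sampled_ids` (the control users drawn).
#' @export
balance_with_controls <- function(positives, negatives, control_pool,
                                  seed = 1L) {
  n_pos <- nrow(positives)
  n_neg <- nrow(negatives)
  if (n_pos < n_neg) {
    stop("expected at least as many positives (", n_pos,
         ") as negatives (", n_neg, ")", call. = FALSE)
  }
  if (length(intersect(negatives$user_id, control_pool$user_id)) > 0) {
    stop("control pool overlaps the negative class", call. = FALSE)
  }
  deficit <- n_pos - n_neg
  if (nrow(control_pool) < deficit) {
    stop("control pool has ", nrow(control_pool),
         " users but ", deficit, " are needed", call. = FALSE)
  }
  sampled <- if (deficit > 0) {
    withr::with_seed(seed,
      control_pool[sample.int(nrow(control_pool), deficit), , drop = FALSE])
  } else {
    control_pool[0, , drop = FALSE]
  }
  dataset <- dplyr::bind_rows(
    dplyr::mutate(positives, label = 1L),
    dplyr::mutate(negatives, label = 0L),
    dplyr::mutate(sampled, label = 0L)
  )
  stopifnot(sum(dataset$label == 1) == sum(dataset$label == 0))
  list(dataset = dataset, sampled_ids = sampled$user_id)
}

#' Align two balanced task datasets into label-homogeneous pairs
#'
#' Pairs each positive user of task A with a positive user of task B (and
#' negatives with negatives) through a seeded random permutation within
#' class, so that every row of the result satisfies
#' `label_a == label_b`. This positive-with-positive alignment is what
#' makes the soft-sharing distance between the two task vectors meaningful.
#'
#' @param ds_a,ds_b Tibbles with a binary `label` column and equal
#'   per-class counts.
#' @param seed Integer seed for the within-class permutation; use
#'   `identity = TRUE` for the order-preserving pairing.
#' @param identity If `TRUE`, pair rows in stored order within class.
#' @return A tibble with columns from A suffixed `_a`, columns from B
#'   suffixed `_b`, and a single `label` column.
#' @export
align_tasks <- function(ds_a, ds_b, seed = 1L, identity = FALSE) {
  counts_a <- table(factor(ds_a$label, levels = c(0, 1)))
  counts_b <- table(factor(ds_b$label, levels = c(0, 1)))
  if (!all(counts_a == counts_b)) {
    stop("class counts differ between tasks: A has ",
         counts_a[["1"]], "+/", counts_a[["0"]], "-, B has ",
         counts_b[["1"]], "+/", counts_b[["0"]], "-", call. = FALSE)
  }
  rows <- withr::with_seed(seed, {
    purrr::map(c(1L, 0L), function(cl) {
      ia <- which(ds_a$label == cl)
      ib <- which(ds_b$label == cl)
      if (!identity && length(ib) > 1) ib <- sample(ib)
      list(a = ia, b = ib)
    })
  })
  ia <- c(rows[[1]]$a, rows[[2]]$a)
  ib <- c(rows[[1]]$b, rows[[2]]$b)
  a <- ds_a[ia, , drop = FALSE]
  b <- ds_b[ib, , drop = FALSE]
  label <- a$label
  a <- dplyr::rename_with(dplyr::select(a, -"label"), ~ paste0(.x, "_a"))
  b <- dplyr::rename_with(dplyr::select(b, -"label"), ~ paste0(.x, "_b"))
  out <- dplyr::bind_cols(a, b)
  out$label <- label
  stopifnot(all(ds_a$label[ia] == ds_b$label[ib]))
  tibble::as_tibble(out)
}

#' Split specification
#'
#' @param n_splits Number of stratified shuffle splits (default 5).
#' @param train_fraction Fraction of rows used for training (default 0.8).
#' @param seed Integer seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(n_splits = 5L, train_fraction = 0.8, seed = 1L) {
  stopifnot(n_splits >= 1, train_fraction > 0, train_fraction < 1)
  structure(list(n_splits = as.integer(n_splits),
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified shuffle splits
#'
#' Draws `n_splits` independent seeded train/validation partitions of the
#' row indices, each preserving the class ratio of `labels` in both parts
#' to within one row. Rows of an aligned pair dataset move as units (the
#' labels agree within a row, so pair rows are the sampling unit).
#'
#' @param labels Binary label vector (one per row).
#' @param spec A [split_spec()].
#' @return A list of `n_splits` lists with integer index vectors `train`
#'   and `val`.
#' @export
stratified_shuffle_splits <- function(labels, spec = split_spec()) {
  n <- length(labels)
  if (n == 0) stop("empty dataset", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop("both classes must be present for stratification", call. = FALSE)
  }
  n_train <- round(spec$train_fraction * n)
  idx_by_class <- lapply(classes, function(cl) which(labels == cl))
  n_class <- lengths(idx_by_class)
  # per-class train counts: floors, then largest fractional remainders
  exact <- spec$train_fraction * n_class
  base <- floor(exact)
  rem <- max(n_train - sum(base), 0)
  if (rem > 0) {
    order_frac <- order(exact - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  if (any(base < 1) || any(n_class - base < 1)) {
    stop("a class has too few rows to appear in both train and ",
         "validation parts", call. = FALSE)
  }
  lapply(seq_len(spec$n_splits), function(s) {
    withr::with_seed(spec$seed + s - 1L, {
      parts <- purrr::map2(idx_by_class, base, function(idx, k) {
        idx <- sample(idx)
        list(train = idx[seq_len(k)], val = idx[-seq_len(k)])
      })
      list(
        train = sort(unlist(purrr::map(parts, "train"))),
        val = sort(unlist(purrr::map(parts, "val")))
      )
    })
  })
}

#' Build a vocabulary from the training documents of both tasks
#'
#' Tokens are ranked by pooled frequency across the two tasks' training
#' documents (ties broken lexicographically) and the top `max_size - 2`
#' are kept. Index 0 is reserved for padding and index 1 for
#' out-of-vocabulary tokens; real tokens get dense indices from 2.
#'
#' @param train_docs_a,train_docs_b Lists of token vectors (or tibbles
#'   with a `tokens` list column).
#' @param max_size Vocabulary size cap including the two reserved indices
#'   (default 20000).
#' @return An object of class `mtl_vocabulary`: a named integer vector
#'   token -> index.
#' @export
build_vocabulary <- function(train_docs_a, train_docs_b = NULL,
                             max_size = 20000L) {
  if (max_size < 3) stop("max_size must be at least 3", call. = FALSE)
  get_tokens <- function(x) {
    if (is.data.frame(x)) x <- x$tokens
    unlist(x, use.names = FALSE)
  }
  pooled <- c(get_tokens(train_docs_a),
              if (!is.null(train_docs_b)) get_tokens(train_docs_b))
  if (length(pooled) == 0) {
    return(structure(setNames(integer(0), character(0)),
                     max_size = as.integer(max_size),
                     class = "mtl_vocabulary"))
  }
  freq <- table(pooled)
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  kept <- names(freq)[ord][seq_len(min(length(freq), max_size - 2L))]
  structure(setNames(seq_along(kept) + 1L, kept),
            max_size = as.integer(max_size),
            class = "mtl_vocabulary")
}

#' @export
print.mtl_vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d tokens (+2 reserved), cap %d>\n",
              length(x), attr(x, "max_size")))
  invisible(x)
}

#' Encode token sequences to fixed-length index vectors
#'
#' Tokens map to their vocabulary index (out-of-vocabulary tokens to 1);
#' sequences longer than `max_len` are truncated keeping the first
#' (chronologically earliest) `max_len` tokens by default; shorter
#' sequences are right-padded with 0.
#'
#' @param tokens A character vector of tokens, or a list of such vectors.
#' @param vocab An [build_vocabulary()] result.
#' @param max_len Output sequence length.
#' @param truncate `"head"` keeps the earliest tokens, `"tail"` the
#'   latest.
#' @return An integer matrix with `max_len` columns (one row per
#'   document), or a single integer vector if `tokens` was one.
#' @export
encode_and_pad <- function(tokens, vocab, max_len,
                           truncate = c("head", "tail")) {
  truncate <- match.arg(truncate)
  stopifnot(max_len >= 1)
  single <- !is.list(tokens)
  if (single) tokens <- list(tokens)
  rows <- lapply(tokens, function(t) {
    idx <- unname(vocab[t])
    idx[is.na(idx)] <- 1L
    if (length(idx) > max_len) {
      idx <- if (truncate == "head") idx[seq_len(max_len)]
             else idx[(length(idx) - max_len + 1L):length(idx)]
    } else if (length(idx) < max_len) {
      idx <- c(idx, rep(0L, max_len - length(idx)))
    }
    idx
  })
  out <- do.call(rbind, rows)
  storage.mode(out) <- "integer"
  if (single) out[1, ] else out
}

#' Decode an index sequence back to tokens
#'
#' Inverse of [encode_and_pad()] for in-vocabulary entries; padding is
#' dropped and out-of-vocabulary indices decode to `"<oov>"`.
#'
#' @param x Integer vector of indices.
#' @param vocab The vocabulary used to encode.
#' @return Character vector of tokens.
#' @export
decode_sequence <- function(x, vocab) {
  inv <- names(vocab)
  x <- x[x != 0L]
  out <- character(length(x))
  out[x == 1L] <- "<oov>"
  out[x >= 2L] <- inv[x[x >= 2L] - 1L]
  out
}

#' Default sequence length: a quantile of training document lengths
#'
#' The concatenated user documents are long and heavy-tailed; bounding the
#' encoded length at the 95th percentile of training lengths covers most
#' users while keeping memory bounded. A hard cap can be supplied.
#'
#' @param docs Tibble with an `n_tokens` column (or an integer vector).
#' @param q Quantile (default 0.95).
#' @param cap Optional upper bound on the returned length.
#' @return Integer sequence length.
#' @export
suggest_max_len <- function(docs, q = 0.95, cap = NULL) {
  n <- if (is.data.frame(docs)) docs$n_tokens else docs
  len <- as.integer(ceiling(quantile(n, q, names = FALSE)))
  if (!is.null(cap)) len <- min(len, as.integer(cap))
  max(len, 1L)
}
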