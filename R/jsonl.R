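#' Read / write a user corpus as line-delimited JSON
#'
#' One JSON object per user:
#' `{"user_id", "platform", "label", "split", "posts": [{"t", "text"}, ...]}`
#' (`split` is optional). Reading returns the post-level tibble layout
#' used throughout the package (one row per post).
#'
#' @param path File path.
#' @return `read_corpus_jsonl`: a tibble with columns `user_id`,
#'   `platform`, `label`, (`split`,) `t`, `text`.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    posts <- tibble::as_tibble(obj$posts)
    out <- tibble::tibble(
      user_id = obj$user_id,
      platform = obj$platform %||% "reddit",
      label = obj$label %||% NA_character_,
      t = posts$t,
      text = posts$text
    )
    if (!is.null(obj$split)) out$split <- obj$split
    out
  })
}

#' @param corpus Post-level tibble (`user_id`, `platform`, `label`, `t`,
#'   `text`, optionally `split`).
#' @rdname read_corpus_jsonl
#' @export
write_corpus_jsonl <- function(corpus, path) {
  users <- split(corpus, factor(corpus$user_id,
                                levels = unique(corpus$user_id)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (u in users) {
    obj <- list(
      user_id = u$user_id[1],
      platform = u$platform[1],
      label = u$label[1],
      posts = purrr::map2(u$t, u$text, ~ list(t = .x, text = .y))
    )
    if ("split" %in% names(u)) obj$split <- u$split[1]
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read / write processed user documents as line-delimited JSON
#'
#' One object per user:
#' `{"user_id", "platform", "label", "tokens": [...]}`.
#'
#' @param path File path.
#' @return `read_documents_jsonl`: a tibble with a `tokens` list column
#'   and `n_tokens`.
#' @export
read_documents_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    out <- tibble::tibble(
      user_id = obj$user_id,
      platform = obj$platform %||% "reddit",
      label = obj$label %||% NA_character_,
      tokens = list(as.character(obj$tokens))
    )
    if (!is.null(obj$split)) out$split <- obj$split
    out$n_tokens <- length(obj$tokens)
    out
  })
}

#' @param docs Tibble from [build_user_documents()].
#' @rdname read_documents_jsonl
#' @export
write_documents_jsonl <- function(docs, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(docs))) {
    obj <- list(
      user_id = docs$user_id[i],
      platform = if ("platform" %in% names(docs)) docs$platform[i]
                 else "reddit",
      label = if ("label" %in% names(docs)) docs$label[i]
              else NA_character_,
      tokens = docs$tokens[[i]]
    )
    if ("split" %in% names(docs)) obj$split <- docs$split[i]
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"),
               con)
  }
  invisible(path)
}
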