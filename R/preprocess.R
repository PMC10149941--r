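#' Cleaning configuration
#'
#' Bundles everything the deterministic preprocessing chain needs: the
#' frozen stopword list (personal pronouns exempted), the contraction
#' table, the tokenizer dialect, and the minimum-token filter threshold
#' (50 tokens for disorder-side/Reddit-style corpora, 20 for tweet-style
#' corpora).
#'
#' @param platform `"reddit"`, `"twitter"` or `"synthetic"`. Chooses the
#'   tokenizer dialect (`tweet_rules` for Twitter, `generic_rules`
#'   otherwise) and the default `min_tokens` (20 for Twitter, 50
#'   otherwise).
#' @param min_tokens Minimum token count a user document must reach to be
#'   kept; counted after cleaning and stopword removal (the count that
#'   reaches the model). Override to change the platform default.
#' @param stopword_list Character vector of stopwords. Defaults to the
#'   frozen list shipped with the package.
#' @param pronouns_kept Personal pronouns that are never removed even if
#'   present in `stopword_list`.
#' @param contraction_table Named character vector mapping contractions to
#'   expansions. Defaults to the frozen table shipped with the package.
#' @param count_after_stopwords Whether `min_tokens` applies to the count
#'   after stopword removal (default) or before.
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(platform = c("reddit", "twitter", "synthetic"),
                            min_tokens = NULL,
                            stopword_list = default_stopwords(),
                            pronouns_kept = personal_pronouns(),
                            contraction_table = default_contractions(),
                            count_after_stopwords = TRUE) {
  platform <- match.arg(platform)
  if (is.null(min_tokens)) {
    min_tokens <- if (platform == "twitter") 20L else 50L
  }
  stopifnot(min_tokens >= 1)
  structure(
    list(
      platform = platform,
      tokenizer_kind = if (platform == "twitter") "tweet_rules"
                       else "generic_rules",
      min_tokens = as.integer(min_tokens),
      stopword_list = stopword_list,
      pronouns_kept = pronouns_kept,
      contraction_table = contraction_table,
      count_after_stopwords = count_after_stopwords
    ),
    class = "cleaning_config"
  )
}

#' Frozen English stopword list (pronouns excluded)
#' @return Character vector.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "mtlrisk")
  words <- readLines(path, encoding = "UTF-8")
  words[!startsWith(words, "#") & nzchar(words)]
}

#' First-, second- and third-person personal pronouns
#'
#' Subject, object, possessive and reflexive forms; these are always kept
#' during stopword removal because pronoun usage (first-person singular in
#' particular) is informative for mental-health text classification.
#' @return Character vector.
#' @export
personal_pronouns <- function() {
  c(
    "i", "me", "my", "mine", "myself",
    "we", "us", "our", "ours", "ourselves",
    "you", "your", "yours", "yourself", "yourselves",
    "he", "him", "his", "himself",
    "she", "her", "hers", "herself",
    "it", "its", "itself",
    "they", "them", "their", "theirs", "themselves"
  )
}

#' Frozen contraction-expansion table
#' @return Named character vector (`names` are the contractions).
#' @export
default_contractions <- function() {
  path <- system.file("extdata", "contractions.csv", package = "mtlrisk")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  setNames(tab$expansion, tab$contraction)
}

# ASCII emoticon pattern: an "eyes" character, optional nose, one or more
# "mouth" characters -- and the reversed (mouth-first) form -- matched only
# as a standalone token.
EMOTICON_REGEX <- paste0(
  "(?<=^|\\s)(?:",
  "[:;=8xX][-o'^]?[)(\\]\\[dDpP/\\\\|*3oO]+",
  "|[)(\\]\\[dD]+[-o'^]?[:;=8]",
  "|<3|</3",
  ")(?=\\s|$)"
)

# Emoji and pictograph ranges plus variation selectors / ZWJ.
EMOJI_REGEX <- paste0(
  "[\\x{1F000}-\\x{1FAFF}\\x{2600}-\\x{27BF}\\x{2190}-\\x{21FF}",
  "\\x{2B00}-\\x{2BFF}\\x{FE00}-\\x{FE0F}\\x{200D}\\x{20E3}]|\\p{So}"
)

expand_contractions <- function(text, table) {
  # Token-wise lookup (faster than one regex per contraction): split on
  # whitespace, replace known apostrophe forms, re-join. Unknown forms are
  # left intact and lose their apostrophe at punctuation stripping.
  pieces <- stringr::str_split(text, "\\s+")
  vapply(pieces, function(tok) {
    hit <- match(tok, names(table))
    tok[!is.na(hit)] <- table[hit[!is.na(hit)]]
    paste(tok, collapse = " ")
  }, character(1))
}

#' Clean raw post text
#'
#' Deterministic cleaning: URLs, @mentions, #hashtags (the whole token),
#' retweet markers, emoticons, emoji and digit sequences are removed; the
#' text is lowercased; contractions are expanded (before punctuation
#' stripping, which would destroy the apostrophes they need); remaining
#' punctuation is replaced by spaces; runs of whitespace, newlines and tabs
#' collapse to single spaces. Cleaning is idempotent and may return an
#' empty string, in which case the caller drops the post.
#'
#' @param text Character vector of raw post texts.
#' @param config A [cleaning_config()].
#' @return Character vector of cleaned texts.
#' @export
#' @examples
#' cfg <- cleaning_config("twitter")
#' clean_text("RT @amy Check http://t.co/x #sad I'm tired!!! 123", cfg)
clean_text <- function(text, config = cleaning_config()) {
  x <- as.character(text)
  x[is.na(x)] <- ""
  x <- stringr::str_replace_all(x, "’", "'")
  x <- stringr::str_remove_all(x, "(?i)\\b(?:https?://|www\\.)\\S+")
  # retweet marker immediately preceding a mention, then mentions/hashtags
  x <- stringr::str_remove_all(x, "(?i)\\brt\\b(?=\\s*@)")
  x <- stringr::str_remove_all(x, "@[A-Za-z0-9_]+")
  x <- stringr::str_remove_all(x, "#\\w+")
  x <- stringr::str_remove_all(x, EMOTICON_REGEX)
  x <- stringr::str_remove_all(x, EMOJI_REGEX)
  x <- stringr::str_remove_all(x, "\\d+")
  # any leading retweet markers left standalone at the start
  x <- stringr::str_remove(x, "^(\\s*(?i:rt)(?=\\s|$))+")
  x <- stringr::str_to_lower(x)
  x <- expand_contractions(x, config$contraction_table)
  x <- stringr::str_replace_all(x, "[^\\p{Ll}\\p{Lo}\\s]", " ")
  x <- stringr::str_squish(x)
  x
}

#' Tokenize cleaned text
#'
#' Whitespace tokenization. The two dialects (`tweet_rules` for
#' tweet-style text, `generic_rules` otherwise) coincide after full
#' cleaning, because cleaning has already expanded the apostrophe forms
#' and stripped the punctuation that the dialects treat differently.
#'
#' @param text Character vector of cleaned text.
#' @param tokenizer_kind `"tweet_rules"` or `"generic_rules"`.
#' @return A list of character vectors (one per input string).
#' @export
tokenize_text <- function(text,
                          tokenizer_kind = c("generic_rules",
                                             "tweet_rules")) {
  tokenizer_kind <- match.arg(tokenizer_kind)
  toks <- stringr::str_split(stringr::str_squish(text), " ")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Remove stopwords, keeping personal pronouns
#'
#' Every token present in the stopword list and absent from the kept
#' pronoun set is dropped; relative order is preserved.
#'
#' @param tokens A character vector of tokens, or a list of such vectors.
#' @param config A [cleaning_config()].
#' @return Same shape as `tokens`.
#' @export
remove_stopwords <- function(tokens, config = cleaning_config()) {
  removal <- setdiff(config$stopword_list, config$pronouns_kept)
  if (is.list(tokens)) {
    lapply(tokens, function(t) t[!t %in% removal])
  } else {
    tokens[!tokens %in% removal]
  }
}

#' Build one document per user from raw posts
#'
#' Posts are sorted by timestamp within each user, cleaned, tokenized and
#' stopword-filtered; posts that clean to an empty string are dropped; the
#' surviving token sequences are concatenated in chronological order into
#' one document per user. User-level metadata columns (`platform`, `label`,
#' and any others constant within a user) are carried through.
#'
#' @param posts A data frame with columns `user_id`, `t` (sortable
#'   timestamp), `text`, and optionally `platform`, `label` and other
#'   user-level metadata.
#' @param config A [cleaning_config()].
#' @return A tibble with one row per user: `user_id`, metadata columns,
#'   `tokens` (list column) and `n_tokens`.
#' @export
build_user_documents <- function(posts, config = cleaning_config()) {
  stopifnot(all(c("user_id", "t", "text") %in% names(posts)))
  posts <- dplyr::arrange(posts, .data$user_id, .data$t)
  cleaned <- clean_text(posts$text, config)
  toks <- tokenize_text(cleaned, config$tokenizer_kind)
  toks <- remove_stopwords(toks, config)

  meta_cols <- setdiff(names(posts), c("t", "text"))
  docs <- posts |>
    dplyr::select(dplyr::all_of(meta_cols)) |>
    dplyr::mutate(.tokens = toks) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(setdiff(meta_cols, "user_id")),
                    dplyr::first),
      tokens = list(unlist(.tokens, use.names = FALSE)),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_tokens = lengths(.data$tokens))
  docs
}

#' Keep only users with enough tokens
#'
#' Retains exactly the users whose documents contain at least `min_tokens`
#' tokens (a user with 49 tokens fails a threshold of 50; one with exactly
#' 50 passes), preserving input order. Never lengthens the input and is
#' idempotent.
#'
#' @param docs A tibble from [build_user_documents()] (needs `n_tokens`).
#' @param min_tokens Positive integer threshold.
#' @return Filtered tibble.
#' @export
filter_min_tokens <- function(docs, min_tokens) {
  stopifnot(min_tokens >= 1, "n_tokens" %in% names(docs))
  dplyr::filter(docs, .data$n_tokens >= min_tokens)
}
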