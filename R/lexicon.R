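#' Construct a category lexicon
#'
#' A lexicon maps category names (e.g. `"sadness"`) to sets of terms.
#' Category scores of a document are term counts within each category,
#' optionally normalised by document length; they serve as auxiliary
#' model inputs.
#'
#' @param categories Named list of character vectors (category name ->
#'   terms). Names must be unique, term sets nonempty. Terms containing a
#'   space are matched as token bigrams.
#' @param name Lexicon name.
#' @return An object of class `mtl_lexicon`.
#' @export
lexicon <- function(categories, name = "lexicon") {
  stopifnot(is.list(categories), length(categories) > 0)
  if (anyDuplicated(names(categories)) || is.null(names(categories)) ||
      any(!nzchar(names(categories)))) {
    stop("category names must be present and unique", call. = FALSE)
  }
  if (any(lengths(categories) == 0)) {
    stop("every category needs at least one term", call. = FALSE)
  }
  structure(list(name = name,
                 categories = lapply(categories, as.character)),
            class = "mtl_lexicon")
}

#' @export
print.mtl_lexicon <- function(x, ...) {
  cat(sprintf("<lexicon '%s': %d categories, %d terms>\n", x$name,
              length(x$categories), sum(lengths(x$categories))))
  invisible(x)
}

#' Read / write a lexicon as JSON
#'
#' File format: `{"name": ..., "categories": {"sadness": ["sad", ...]}}`.
#'
#' @param path File path.
#' @return `read_lexicon` returns an `mtl_lexicon`.
#' @export
read_lexicon <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lexicon(as.list(obj$categories), name = obj$name %||% "lexicon")
}

#' @param lex An `mtl_lexicon`.
#' @rdname read_lexicon
#' @export
write_lexicon <- function(lex, path) {
  jsonlite::write_json(list(name = lex$name, categories = lex$categories),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score documents against lexicon categories
#'
#' The raw score of category `c` for a document is the number of tokens
#' (and, for multi-word terms, token bigrams) belonging to `c`'s term
#' set. With `normalize = TRUE` (the default) scores are divided by the
#' document token count; an empty document scores zero everywhere (0/0 is
#' defined as 0). Scores are invariant to token order (up to bigram terms).
#'
#' @param docs A tibble with `user_id` and a `tokens` list column (as from
#'   [build_user_documents()]), or a bare list of token vectors.
#' @param lex An [lexicon()] object.
#' @param normalize Divide counts by document length.
#' @return A tibble: `user_id` plus one numeric column per category, in
#'   lexicon category order.
#' @export
score_categories <- function(docs, lex, normalize = TRUE) {
  if (is.data.frame(docs)) {
    ids <- docs$user_id
    token_list <- docs$tokens
  } else {
    token_list <- docs
    ids <- paste0("doc_", seq_along(token_list))
  }
  cat_names <- names(lex$categories)
  uni <- lapply(lex$categories, function(t) t[!grepl(" ", t, fixed = TRUE)])
  bi <- lapply(lex$categories, function(t) t[grepl(" ", t, fixed = TRUE)])
  has_bi <- any(lengths(bi) > 0)

  scores <- vapply(token_list, function(tok) {
    n <- length(tok)
    counts <- vapply(cat_names, function(cn) {
      s <- sum(tok %in% uni[[cn]])
      if (has_bi && length(bi[[cn]]) > 0 && n >= 2) {
        bigrams <- paste(tok[-n], tok[-1])
        s <- s + sum(bigrams %in% bi[[cn]])
      }
      as.numeric(s)
    }, numeric(1))
    if (normalize) {
      if (n == 0) counts[] <- 0 else counts <- counts / n
    }
    counts
  }, numeric(length(cat_names)))

  out <- tibble::as_tibble(t(matrix(scores, nrow = length(cat_names),
                                    dimnames = list(cat_names, NULL))))
  dplyr::bind_cols(tibble::tibble(user_id = ids), out)
}

#' Fit a feature scaler on training features
#'
#' Per-dimension min-max scaling fitted on training features only: the
#' training minimum maps to 0 and the maximum to 1; at transform time
#' values are clipped into `[0, 1]`, and constant training dimensions map
#' to 0 everywhere. A z-score variant is available.
#'
#' @param features A numeric matrix or a tibble of numeric columns
#'   (non-numeric columns such as `user_id` are ignored but remembered).
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return An object of class `mtl_scaler`.
#' @export
fit_scaler <- function(features, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  m <- as_feature_matrix(features)
  if (nrow(m) == 0) stop("no training features", call. = FALSE)
  structure(
    list(
      method = method,
      columns = colnames(m),
      min = apply(m, 2, min),
      max = apply(m, 2, max),
      mean = colMeans(m),
      sd = apply(m, 2, stats::sd)
    ),
    class = "mtl_scaler"
  )
}

as_feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  num <- dplyr::select(features, dplyr::where(is.numeric))
  as.matrix(num)
}

#' Apply (or invert) a fitted scaler
#'
#' @param scaler An [fit_scaler()] result.
#' @param features Matrix or tibble with the same feature columns.
#' @param inverse Map scaled values back to the original range
#'   (identity on the training range for the forward transform).
#' @return Object of the same shape as `features` with scaled values.
#' @export
apply_scaler <- function(scaler, features, inverse = FALSE) {
  m <- as_feature_matrix(features)
  if (ncol(m) != length(scaler$columns) ||
      (!is.null(colnames(m)) && !identical(colnames(m), scaler$columns))) {
    stop("feature dimensions do not match the fitted scaler (",
         ncol(m), " vs ", length(scaler$columns), ")", call. = FALSE)
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    if (scaler$method == "minmax") {
      rng <- scaler$max[j] - scaler$min[j]
      if (inverse) {
        out[, j] <- if (rng == 0) scaler$min[j] else
          m[, j] * rng + scaler$min[j]
      } else {
        out[, j] <- if (rng == 0) 0 else
          pmin(pmax((m[, j] - scaler$min[j]) / rng, 0), 1)
      }
    } else {
      s <- scaler$sd[j]
      if (inverse) {
        out[, j] <- if (s == 0) scaler$mean[j] else
          m[, j] * s + scaler$mean[j]
      } else {
        out[, j] <- if (s == 0) 0 else (m[, j] - scaler$mean[j]) / s
      }
    }
  }
  if (is.matrix(features)) {
    out
  } else {
    res <- features
    res[, scaler$columns] <- tibble::as_tibble(out)
    res
  }
}

PRESET_CATEGORIES <- list(
  # 14 categories used as auxiliary input for the flagged/not flagged task
  flagged14 = c(
    "health", "medical_emergency", "sadness", "nervousness", "fear",
    "contentment", "domestic_work", "horror", "torment", "suicide_topw",
    "neglect", "shame", "suffering", "sexual"
  ),
  # 6 categories for the urgent/not urgent task
  urgent6 = c("neglect", "anger", "sadness", "torment", "emotional",
              "shame"),
  # 10 categories for the cross-platform (Reddit + Twitter) experiments
  crossplatform10 = c(
    "health", "medical_emergency", "crime", "horror", "war", "sadness",
    "fear", "suffering", "aggression", "neglect"
  )
)

#' Published auxiliary-category presets
#'
#' The three category lists used as auxiliary inputs in the published
#' experiments: 14 categories for the flagged/not flagged task (including
#' the custom `suicide_topw` category), 6 for urgent/not urgent, and 10
#' for the cross-platform experiments. The preset carries only the
#' category names, in printed order; term inventories come from a lexicon
#' file (categories the lexicon lacks are an error at featurisation time).
#'
#' @param name `"flagged14"`, `"urgent6"` or `"crossplatform10"`.
#' @return An object of class `category_preset` with fields `name` and
#'   `categories`.
#' @export
load_preset <- function(name = c("flagged14", "urgent6",
                                 "crossplatform10")) {
  name <- match.arg(name)
  structure(list(name = name, categories = PRESET_CATEGORIES[[name]]),
            class = "category_preset")
}

#' Restrict a lexicon to a category preset
#'
#' @param lex An [lexicon()].
#' @param preset A [load_preset()] result (or preset name).
#' @return An `mtl_lexicon` containing the preset categories in preset
#'   order.
#' @export
apply_preset <- function(lex, preset) {
  if (is.character(preset)) preset <- load_preset(preset)
  missing <- setdiff(preset$categories, names(lex$categories))
  if (length(missing) > 0) {
    stop("lexicon lacks preset categories: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lexicon(lex$categories[preset$categories],
          name = paste0(lex$name, ":", preset$name))
}
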