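#' Published annotation counts for the UMD Reddit Suicidality corpus
#'
#' The printed 4x4 confusion matrix of expert against crowdsourced
#' 4-level risk annotations for the 245 users labelled by both groups.
#' Rows are expert annotations, columns crowdsourced annotations, both
#' ordered none / low / moderate / severe. Collapsing both axes with the
#' flagged rule gives a positive-class F1 of 382/407 (printed as 0.9385),
#' and with the urgent rule 280/331 (printed as 0.8458).
#'
#' @return A [risk_confusion_matrix()].
#' @export
annotation_agreement_counts <- function() {
  risk_confusion_matrix(matrix(c(
    29,  1,  1,  5,
    11, 13, 20,  6,
     6, 11, 47, 51,
     1,  1,  8, 34
  ), 4, 4, byrow = TRUE))
}

#' Published per-class user counts of the suicide-ideation corpus
#'
#' The class distributions of the UMD Reddit Suicidality corpus as
#' assembled for the two screening tasks: per risk level, the number of
#' users in the train, (crowdsourced) test and expert-annotated test
#' partitions, plus the randomly sampled control top-up rows. `positive`
#' marks the classes merged into the positive class for that task.
#'
#' @return A tibble with columns `task`, `split`, `class_label`, `n`,
#'   `positive`.
#' @export
umd_class_distribution <- function() {
  rows <- list(
    # task, split, class_label, n, positive
    list("flagged", "train", "none", 127, FALSE),
    list("flagged", "train", "low", 50, TRUE),
    list("flagged", "train", "moderate", 113, TRUE),
    list("flagged", "train", "severe", 206, TRUE),
    list("flagged", "train", "random_control", 242, FALSE),
    list("flagged", "test", "none", 32, FALSE),
    list("flagged", "test", "low", 13, TRUE),
    list("flagged", "test", "moderate", 28, TRUE),
    list("flagged", "test", "severe", 52, TRUE),
    list("flagged", "test_expert", "none", 36, FALSE),
    list("flagged", "test_expert", "low", 50, TRUE),
    list("flagged", "test_expert", "moderate", 115, TRUE),
    list("flagged", "test_expert", "severe", 44, TRUE),
    list("urgent", "train", "none", 127, FALSE),
    list("urgent", "train", "low", 50, FALSE),
    list("urgent", "train", "moderate", 113, TRUE),
    list("urgent", "train", "severe", 206, TRUE),
    list("urgent", "train", "random_control", 142, FALSE),
    list("urgent", "test", "none", 32, FALSE),
    list("urgent", "test", "low", 13, FALSE),
    list("urgent", "test", "moderate", 28, TRUE),
    list("urgent", "test", "severe", 52, TRUE),
    list("urgent", "test_expert", "none", 36, FALSE),
    list("urgent", "test_expert", "low", 50, FALSE),
    list("urgent", "test_expert", "moderate", 115, TRUE),
    list("urgent", "test_expert", "severe", 44, TRUE)
  )
  purrr::map_dfr(rows, ~ tibble::tibble(
    task = .x[[1]], split = .x[[2]], class_label = .x[[3]],
    n = as.integer(.x[[4]]), positive = .x[[5]]
  ))
}

#' Published annotator-level class counts of the full risk corpus
#'
#' Number of users per risk level and annotator group in the full corpus
#' (crowdsourced and expert annotations), including the control pool the
#' random balancing draws from.
#'
#' @return A tibble with columns `annotator`, `class_label`, `n`.
#' @export
umd_annotator_counts <- function() {
  tibble::tibble(
    annotator = rep(c("crowdsource", "expert"), each = 5),
    class_label = rep(c("none", "low", "moderate", "severe", "control"),
                      2),
    n = as.integer(c(159, 63, 141, 258, 621, 36, 50, 115, 44, 245))
  )
}
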