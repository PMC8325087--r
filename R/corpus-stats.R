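stat_tokens <- function(corpus, stopwords) {
  toks <- tokenize(corpus$text)
  tibble(
    label = rep(as.integer(corpus$label), lengths(toks)),
    word = unlist(toks, use.names = FALSE)
  ) |>
    dplyr::filter(!.data$word %in% stopwords)
}

#' Per-class emotion-word percentages
#'
#' For each class, the percentage of positive-emotion and negative-emotion
#' tokens among all tokens of that class, counted after tokenization and
#' stop-word removal: `100 * emotion-token count / total token count`. A
#' token is positive/negative by the sign of its lexicon score. This is the
#' class-level emotion-rate table that motivates giving the classifier an
#' explicit emotion branch (depressed authors use more negative and fewer
#' positive words).
#'
#' @param corpus Tibble with `text` and `label`.
#' @param lexicon A `polarity_lexicon`.
#' @param stopwords Character vector; defaults to the bundled English list.
#' @return A tibble with one row per class: `label`, `n_tokens`,
#'   `positive_pct`, `negative_pct`.
#' @export
emotion_percentages <- function(corpus, lexicon, stopwords = bundled_stopwords()) {
  stopifnot(nrow(corpus) > 0)
  stat_tokens(corpus, stopwords) |>
    dplyr::mutate(score = lexicon_score(lexicon, .data$word)) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n_tokens = dplyr::n(),
      positive_pct = 100 * mean(.data$score > 0),
      negative_pct = 100 * mean(.data$score < 0),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$label))
}

#' Ranked word-frequency lists per class
#'
#' Counts each word's occurrences per class after stop-word removal and
#' returns three ranked lists per class — all words, positive-lexicon words,
#' negative-lexicon words — truncated to the top `k`. Ranking is by count
#' (descending) with lexicographic tie-break.
#'
#' @inheritParams emotion_percentages
#' @param k Cutoff per list.
#' @return A tibble with `label`, `category` (`all`/`positive`/`negative`),
#'   `word`, `count`, `rank`.
#' @export
word_frequencies <- function(corpus, lexicon, stopwords = bundled_stopwords(),
                             k = 50L) {
  stopifnot(k >= 1)
  counts <- stat_tokens(corpus, stopwords) |>
    dplyr::count(.data$label, .data$word, name = "count") |>
    dplyr::mutate(score = lexicon_score(lexicon, .data$word))
  per_cat <- function(df, category) {
    df |>
      dplyr::group_by(.data$label) |>
      dplyr::arrange(dplyr::desc(.data$count), .data$word, .by_group = TRUE) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::filter(.data$rank <= k) |>
      dplyr::ungroup() |>
      dplyr::mutate(category = category, .after = "label")
  }
  dplyr::bind_rows(
    per_cat(counts, "all"),
    per_cat(dplyr::filter(counts, .data$score > 0), "positive"),
    per_cat(dplyr::filter(counts, .data$score < 0), "negative")
  ) |>
    dplyr::select("label", "category", "word", "count", "rank")
}

#' Fusion-gate share report
#'
#' Summarizes the realized fusion gate theta per post and per class. The gate
#' weighs positive emotional information by `theta` and negative emotional
#' information by `1 - theta`, so a depression-class mean of `1 - theta`
#' above 0.5 means the model leans on negative emotional information for
#' depression-indicative posts — the qualitative pattern the gate is meant
#' to recover.
#'
#' @param diagnostics A tibble containing `theta` and `label` columns (e.g.
#'   from [predict.ean_fit()], [ean_diagnostics()], or the `diagnostics`
#'   element of [cross_validate()]), or a path to a diagnostics JSONL file.
#' @return A list of class `theta_report`: `per_post` (theta and its
#'   complement per post), `per_class` (mean theta and mean `1 - theta` per
#'   class), and `negative_dominant` (`TRUE` when the depression class's
#'   mean `1 - theta` exceeds 0.5).
#' @export
theta_report <- function(diagnostics) {
  if (is.character(diagnostics) && length(diagnostics) == 1L) {
    lines <- readLines(diagnostics, encoding = "UTF-8", warn = FALSE)
    diagnostics <- dplyr::bind_rows(
      purrr::map(lines, ~ as_tibble(jsonlite::fromJSON(.x)[c("theta", "label")]))
    )
  }
  if (!all(c("theta", "label") %in% names(diagnostics))) {
    abort("diagnostics must contain 'theta' and 'label' columns")
  }
  if (all(is.na(diagnostics$theta))) {
    abort(paste0("no realized theta in diagnostics - the model variant has no ",
                 "dynamic fusion gate (e.g. concatenate fusion)"))
  }
  per_post <- tibble(
    label = as.integer(diagnostics$label),
    theta = diagnostics$theta,
    one_minus_theta = 1 - diagnostics$theta
  )
  per_class <- per_post |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_theta = mean(.data$theta),
      mean_one_minus_theta = mean(.data$one_minus_theta),
      .groups = "drop"
    )
  dep <- per_class[per_class$label == 1L, ]
  structure(
    list(per_post = per_post, per_class = per_class,
         negative_dominant = nrow(dep) > 0 && dep$mean_one_minus_theta > 0.5),
    class = "theta_report"
  )
}

#' @export
print.theta_report <- function(x, ...) {
  cat("<theta_report>", nrow(x$per_post), "posts\n")
  print(as.data.frame(x$per_class), digits = 3)
  cat("  negative information dominant for depression class:",
      x$negative_dominant, "\n")
  invisible(x)
}
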