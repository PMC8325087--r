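#' Word-polarity lexicons
#'
#' A polarity lexicon maps each word to a signed real score, typically in
#' \[-1, 1\]: positive scores mark positive-emotion words, negative scores
#' negative-emotion words. It drives the polarity split that feeds the
#' emotion branch of the network. Words absent from the lexicon are neutral
#' (score 0).
#'
#' @param words Character vector of words.
#' @param scores Numeric vector of signed scores, same length.
#' @param name Lexicon name/version string.
#' @return An object of class `polarity_lexicon`.
#' @export
polarity_lexicon <- function(words, scores, name = "custom") {
  stopifnot(length(words) == length(scores), all(is.finite(scores)))
  x <- setNames(as.numeric(scores), as.character(words))
  structure(list(scores = x, name = name), class = "polarity_lexicon")
}

#' @export
print.polarity_lexicon <- function(x, ...) {
  cat("<polarity_lexicon>", x$name, "-", length(x$scores), "words\n")
  invisible(x)
}

#' @export
length.polarity_lexicon <- function(x) length(x$scores)

#' @method as_tibble polarity_lexicon
#' @export
as_tibble.polarity_lexicon <- function(x, ...) {
  tibble(word = names(x$scores), score = unname(x$scores))
}

#' Load a polarity lexicon from a TSV file
#'
#' Format: one `word<TAB>score` pair per line, UTF-8, no header; lines
#' starting with `#` are ignored. Duplicated words keep the last occurrence
#' (with a warning).
#'
#' @param path TSV file path.
#' @param name Optional lexicon name; defaults to the file name.
#' @return A `polarity_lexicon`.
#' @export
load_lexicon <- function(path, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad_shape <- lengths(parts) < 2L
  if (any(bad_shape)) {
    abort(paste0("lexicon line ", idx[which(bad_shape)[1]],
                 ": expected 'word<TAB>score'"))
  }
  words <- vapply(parts, `[[`, character(1), 1L)
  raw <- vapply(parts, `[[`, character(1), 2L)
  scores <- suppressWarnings(as.numeric(raw))
  if (anyNA(scores)) {
    abort(paste0("lexicon line ", idx[which(is.na(scores))[1]],
                 ": unparseable score ", shQuote(raw[which(is.na(scores))[1]])))
  }
  if (anyDuplicated(words)) {
    warn(paste0("duplicate lexicon entries; keeping the last occurrence: ",
                paste(unique(words[duplicated(words)]), collapse = ", ")))
    last <- !duplicated(words, fromLast = TRUE)
    words <- words[last]
    scores <- scores[last]
  }
  polarity_lexicon(words, scores, name = name)
}

#' Look up polarity scores
#'
#' @param lexicon A `polarity_lexicon`.
#' @param words Character vector.
#' @return Numeric scores; 0 for words not in the lexicon.
#' @export
lexicon_score <- function(lexicon, words) {
  s <- lexicon$scores[words]
  s[is.na(s)] <- 0
  unname(s)
}

#' The bundled demonstration lexicon
#'
#' A small word-polarity lexicon (about 100 entries) over high-frequency
#' emotion words of depression-forum language, with hand-assigned signed
#' scores. Intended for examples and tests; real analyses should plug in a
#' full lexicon (e.g. a SenticNet export) via [load_lexicon()].
#'
#' @return A `polarity_lexicon`.
#' @export
bundled_lexicon <- function() {
  path <- system.file("extdata", "demo_lexicon.tsv", package = "emoattn")
  load_lexicon(path, name = "demo")
}

#' The bundled English stop-word list
#'
#' @return Character vector of stop words (used by the corpus statistics,
#'   never by the model input pipeline).
#' @export
bundled_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "emoattn")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Split a token sequence by polarity
#'
#' Routes every token occurrence with a positive lexicon score to the
#' positive side and every occurrence with a negative score to the negative
#' side, preserving the original within-post order. Neutral tokens (score 0
#' or absent from the lexicon) are dropped: the semantic branch already sees
#' the full text, so the emotion branch only receives emotion-bearing words.
#'
#' @param tokens Character vector of tokens (one post).
#' @param lexicon A `polarity_lexicon`.
#' @return A `polarity_split`: list with `pos_tokens`, `neg_tokens` and the
#'   source length `n`.
#' @examples
#' lex <- polarity_lexicon(c("good", "bad"), c(0.8, -0.7))
#' split_by_polarity(c("good", "bad", "day"), lex)
#' @export
split_by_polarity <- function(tokens, lexicon) {
  stopifnot(length(tokens) >= 1L)
  s <- lexicon_score(lexicon, tokens)
  structure(
    list(
      pos_tokens = tokens[s > 0],
      neg_tokens = tokens[s < 0],
      n = length(tokens)
    ),
    class = "polarity_split"
  )
}

#' @export
print.polarity_split <- function(x, ...) {
  cat("<polarity_split> n =", x$n, "\n")
  cat("  pos:", paste(x$pos_tokens, collapse = " "), "\n")
  cat("  neg:", paste(x$neg_tokens, collapse = " "), "\n")
  invisible(x)
}

#' Encode a polarity split for the emotion branch
#'
#' Each side is index-encoded and padded exactly as the full post is. An
#' empty side yields the all-padding sequence with its `empty` flag set, which
#' the downstream encoder turns into a zero context vector so the fusion gate
#' stays well-defined.
#'
#' @param split A `polarity_split`.
#' @param vocab An `ean_vocab`.
#' @param max_len_emo Fixed length for each emotional sub-sequence.
#' @return List with elements `pos` and `neg`, each an `ean_seq`.
#' @export
encode_split <- function(split, vocab, max_len_emo) {
  stopifnot(inherits(split, "polarity_split"), max_len_emo >= 1)
  list(
    pos = new_seq(split$pos_tokens, vocab, max_len_emo, allow_empty = TRUE),
    neg = new_seq(split$neg_tokens, vocab, max_len_emo, allow_empty = TRUE)
  )
}
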