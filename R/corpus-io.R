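#' Read a labeled post corpus
#'
#' Reads a corpus of social-media posts with binary depression labels from
#' JSONL (one `{"text": ..., "label": ...}` object per line) or CSV (header
#' `text,label`). Labels may be strings (mapped through `label_map`,
#' case-insensitively) or already-numeric 0/1.
#'
#' @param path Path to the corpus file.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @param label_map Named integer vector mapping lower-cased label strings to
#'   classes. Class 1 is depression-indicative, class 0 standard.
#' @return A tibble with columns `text` (character) and `label` (integer 0/1),
#'   in file order.
#' @examples
#' f <- tempfile(fileext = ".jsonl")
#' writeLines(c(
#'   '{"text": "i feel so alone", "label": "depression"}',
#'   '{"text": "great day with friends", "label": "standard"}'
#' ), f)
#' read_corpus(f)
#' @export
read_corpus <- function(path,
                        format = c("auto", "jsonl", "csv"),
                        label_map = default_label_map()) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("corpus file not found: ", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- nzchar(trimws(lines))
    recs <- purrr::imap(lines[keep], function(line, i) {
      rec <- tryCatch(
        jsonlite::fromJSON(line),
        error = function(e) abort(paste0("line ", which(keep)[i], ": invalid JSON"))
      )
      if (is.null(rec$text)) abort(paste0("line ", which(keep)[i], ": missing 'text' field"))
      if (is.null(rec$label)) abort(paste0("line ", which(keep)[i], ": missing 'label' field"))
      tibble(text = as.character(rec$text), label_raw = as.character(rec$label))
    })
    out <- dplyr::bind_rows(recs)
    line_no <- which(keep)
  } else {
    out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (!all(c("text", "label") %in% names(out))) {
      abort("CSV corpus must have columns 'text' and 'label'")
    }
    out <- tibble(text = out$text, label_raw = out$label)
    line_no <- seq_len(nrow(out)) + 1L  # header is line 1
  }
  empty <- !nzchar(trimws(out$text)) | is.na(out$text)
  if (any(empty)) {
    abort(paste0("empty post text at line ", line_no[which(empty)[1]]))
  }
  out$label <- map_labels(out$label_raw, label_map)
  tibble(text = out$text, label = out$label)
}

#' @rdname read_corpus
#' @export
default_label_map <- function() {
  c(depression = 1L, standard = 0L, nondepression = 0L, control = 0L,
    "1" = 1L, "0" = 0L)
}

map_labels <- function(raw, label_map) {
  key <- tolower(trimws(raw))
  hit <- match(key, names(label_map))
  if (anyNA(hit)) {
    bad <- unique(raw[is.na(hit)])
    abort(paste0(
      "unknown label value(s): ", paste(shQuote(bad), collapse = ", "),
      "; allowed: ", paste(shQuote(names(label_map)), collapse = ", ")
    ))
  }
  as.integer(unname(label_map[hit]))
}

#' Write a labeled corpus
#'
#' Inverse of [read_corpus()]. JSONL writes labels as the strings
#' `"depression"` / `"standard"`; CSV writes the numeric class.
#'
#' @param corpus Tibble with columns `text` and `label`.
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(all(c("text", "label") %in% names(corpus)))
  if (format == "jsonl") {
    lab <- ifelse(corpus$label == 1L, "depression", "standard")
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(list(text = corpus$text[i], label = lab[i]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    readr::write_csv(corpus[, c("text", "label")], path, progress = FALSE)
  }
  invisible(path)
}

#' Tokenize post text
#'
#' Lower-cases and splits on any character that is not a letter, digit or an
#' internal apostrophe, so contractions such as `"i'm"` and `"can't"` survive
#' as single tokens (typographic apostrophes are normalised first). An input
#' that yields no tokens produces the single unknown token, so every post has
#' length at least one.
#'
#' @param text Character vector of post texts.
#' @return A list of character vectors, one per input element.
#' @examples
#' tokenize("Today, I feel so horrible")
#' @export
tokenize <- function(text) {
  text <- gsub("’", "'", tolower(as.character(text)))
  m <- gregexpr("[\\p{L}\\p{N}]+(?:'[\\p{L}\\p{N}]+)*", text, perl = TRUE)
  toks <- regmatches(text, m)
  purrr::map(toks, function(tk) if (length(tk) == 0L) UNK_TOKEN else tk)
}

#' Build a vocabulary from a corpus
#'
#' Collects every token with frequency at least `min_count` and assigns
#' contiguous 0-based indices: 0 is always the padding token, 1 the unknown
#' token, and the remaining words are ordered by frequency (descending) with
#' lexicographic tie-break, which makes the vocabulary deterministic.
#'
#' @param corpus Tibble with a `text` column (labels are ignored).
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @return An object of class `ean_vocab`.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  stopifnot(is.numeric(min_count), min_count >= 1)
  if (NROW(corpus) == 0L) abort("cannot build a vocabulary from an empty corpus")
  toks <- unlist(tokenize(corpus$text), use.names = FALSE)
  toks <- toks[!toks %in% c(PAD_TOKEN, UNK_TOKEN)]
  tab <- table(toks)
  keep <- tab[tab >= min_count]
  ord <- order(-as.integer(keep), names(keep), method = "radix")
  words <- c(PAD_TOKEN, UNK_TOKEN, names(keep)[ord])
  new_vocab(words)
}

new_vocab <- function(words) {
  idx <- seq_along(words) - 1L
  names(idx) <- words
  structure(list(words = words, index = idx), class = "ean_vocab")
}

#' @export
print.ean_vocab <- function(x, ...) {
  cat("<ean_vocab> size", length(x$words), "\n")
  cat("  ", paste(utils::head(x$words, 8), collapse = " "),
      if (length(x$words) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
length.ean_vocab <- function(x) length(x$words)

#' Map tokens to vocabulary indices
#'
#' @param vocab An `ean_vocab`.
#' @param tokens Character vector of tokens.
#' @return Integer vector of 0-based indices; out-of-vocabulary tokens map to
#'   the unknown index 1.
#' @export
word_ids <- function(vocab, tokens) {
  ids <- vocab$index[tokens]
  ids[is.na(ids)] <- UNK_ID
  as.integer(unname(ids))
}

#' Encode and pad one post
#'
#' Tokenizes (if given raw text), maps tokens to indices, truncates to the
#' first `max_len` tokens and appends padding. The returned mask marks real
#' token positions; downstream encoders never attend to padding.
#'
#' @param x A single post text, or an already-tokenized character vector.
#' @param vocab An `ean_vocab`.
#' @param max_len Fixed sequence length after padding/truncation.
#' @return An `ean_seq`: list with `tokens`, `ids` (0-based, length
#'   `max_len`), `n` (token count before padding, capped at `max_len`),
#'   `mask` (logical), and `empty` flag.
#' @export
encode_and_pad <- function(x, vocab, max_len) {
  stopifnot(max_len >= 1)
  tokens <- if (is.character(x) && length(x) == 1L && !inherits(x, "AsIs")) {
    tokenize(x)[[1]]
  } else {
    as.character(x)
  }
  new_seq(tokens, vocab, max_len, allow_empty = FALSE)
}

new_seq <- function(tokens, vocab, max_len, allow_empty = FALSE) {
  n <- length(tokens)
  if (n == 0L && !allow_empty) {
    tokens <- UNK_TOKEN
    n <- 1L
  }
  n_used <- min(n, max_len)
  kept <- tokens[seq_len(n_used)]
  ids <- c(word_ids(vocab, kept), rep(PAD_ID, max_len - n_used))
  structure(
    list(
      tokens = c(kept, rep(PAD_TOKEN, max_len - n_used)),
      ids = ids,
      n = n_used,
      mask = seq_len(max_len) <= n_used,
      empty = n_used == 0L
    ),
    class = "ean_seq"
  )
}

#' Load word embeddings in GloVe text format
#'
#' Each line of the file is a word followed by `dim` space-separated decimal
#' values. Words present in the vocabulary are copied; the padding row is
#' fixed to zero; every other row (unknown token and misses) is initialized
#' uniformly in (-0.05, 0.05) from `seed` so it stays trainable. With
#' `path = NULL` the whole matrix (except padding) is random — useful when no
#' pretrained file is available, e.g. for synthetic vocabularies.
#'
#' @param path GloVe-format text file, or `NULL` for a random matrix.
#' @param vocab An `ean_vocab`.
#' @param dim Embedding dimension.
#' @param seed Integer seed driving the random rows.
#' @return A `V x dim` numeric matrix with attribute `provenance`
#'   (`"pretrained"` or `"random"`).
#' @export
load_embeddings <- function(path, vocab, dim, seed = 0L) {
  V <- length(vocab$words)
  emb <- withr::with_seed(seed, {
    matrix(runif(V * dim, -0.05, 0.05), nrow = V, ncol = dim)
  })
  provenance <- "random"
  if (!is.null(path)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    for (i in seq_along(lines)) {
      if (!nzchar(lines[i])) next
      parts <- strsplit(lines[i], " +")[[1]]
      if (length(parts) != dim + 1L) {
        abort(paste0("embedding line ", i, ": expected ", dim,
                     " values, found ", length(parts) - 1L))
      }
      w <- parts[1]
      row <- match(w, vocab$words)
      if (!is.na(row)) {
        vals <- suppressWarnings(as.numeric(parts[-1]))
        if (anyNA(vals)) abort(paste0("embedding line ", i, ": non-numeric value"))
        emb[row, ] <- vals
      }
    }
    provenance <- "pretrained"
  }
  emb[PAD_ID + 1L, ] <- 0
  attr(emb, "provenance") <- provenance
  emb
}
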