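test_that("JSONL corpora are parsed in file order with mapped labels", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"text": "i feel awful", "label": "depression"}',
    '{"text": "lovely weather", "label": "Standard"}'
  ), f)
  corp <- read_corpus(f)
  expect_equal(nrow(corp), 2L)
  expect_equal(corp$label, c(1L, 0L))
  expect_equal(corp$text[2], "lovely weather")
})

test_that("CSV corpora map labels and count classes correctly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("text,label", "sad post,depression", "worse post,depression",
               "fine post,standard"), f)
  corp <- read_corpus(f)
  expect_equal(unname(table(corp$label)[c("1", "0")]), c(2L, 1L),
               ignore_attr = TRUE)
})

test_that("malformed corpus records produce record-level errors", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"text": "ok", "label": "depression"}',
               '{"text": "   ", "label": "standard"}'), f)
  expect_error(read_corpus(f), "line 2")

  f2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"label": "depression"}', f2)
  expect_error(read_corpus(f2), "missing 'text'")

  f3 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"text": "hi", "label": "bogus"}', f3)
  expect_error(read_corpus(f3), "allowed.*depression")
})

test_that("JSONL write/read round trip reproduces text and labels exactly", {
  corp <- tiny_corpus()
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp, f)
  expect_equal(read_corpus(f), corp)
})

test_that("tokenizer lowercases, keeps contractions, and never returns empty", {
  expect_equal(tokenize("Today, I feel so horrible")[[1]],
               c("today", "i", "feel", "so", "horrible"))
  expect_equal(tokenize("I'm can't")[[1]], c("i'm", "can't"))
  expect_equal(tokenize("I’m fine!")[[1]], c("i'm", "fine"))
  expect_equal(tokenize("")[[1]], "<unk>")
  expect_equal(tokenize("?!...")[[1]], "<unk>")
})

test_that("vocabulary respects min_count and the frequency/lexicographic order", {
  corp <- tibble::tibble(text = "a a b")
  v1 <- build_vocab(corp, min_count = 1)
  expect_equal(v1$words, c("<pad>", "<unk>", "a", "b"))
  v2 <- build_vocab(corp, min_count = 2)
  expect_equal(v2$words, c("<pad>", "<unk>", "a"))
  # equal counts break ties lexicographically
  v3 <- build_vocab(tibble::tibble(text = "zeta alpha zeta alpha mid"))
  expect_equal(word_ids(v3, "alpha") < word_ids(v3, "zeta"), TRUE)
  expect_error(build_vocab(tibble::tibble(text = character(0))), "empty")
})

test_that("embedding loader copies hits, zeroes padding, and is reproducible", {
  v <- new_vocab <- build_vocab(tibble::tibble(text = "good day"))
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("good 1.0 0.0", f)
  emb <- load_embeddings(f, v, dim = 2, seed = 7)
  expect_equal(emb[word_ids(v, "good") + 1L, ], c(1, 0))
  expect_equal(emb[1L, ], c(0, 0))
  expect_identical(attr(emb, "provenance"), "pretrained")
  expect_identical(emb, load_embeddings(f, v, dim = 2, seed = 7))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("good 1.0 0.0", "day 1 2 3"), f2)
  expect_error(load_embeddings(f2, v, dim = 2), "line 2")

  r <- load_embeddings(NULL, v, dim = 4, seed = 1)
  expect_identical(attr(r, "provenance"), "random")
  expect_true(all(abs(r[-1L, ]) <= 0.05) && all(is.finite(r)))
})

test_that("encode_and_pad pads, truncates from the head, and maps OOV to unk", {
  v <- build_vocab(tibble::tibble(text = "one two three four five six seven"))
  s <- encode_and_pad("one two three", v, max_len = 5)
  expect_equal(length(s$ids), 5L)
  expect_equal(s$ids[4:5], c(0L, 0L))
  expect_equal(s$n, 3L)

  s2 <- encode_and_pad("one two three four five six seven", v, max_len = 5)
  expect_equal(s2$tokens, c("one", "two", "three", "four", "five"))

  s3 <- encode_and_pad("quux zork", v, max_len = 3)
  expect_equal(s3$ids, c(1L, 1L, 0L))
})

test_that("padded length and pad count hold over random posts", {
  v <- build_vocab(tiny_corpus())
  withr::with_seed(4, {
    for (i in 1:25) {
      n <- sample(1:30, 1)
      txt <- paste(sample(c("feel", "alone", "day", "walk"), n, TRUE),
                   collapse = " ")
      max_len <- sample(1:20, 1)
      s <- encode_and_pad(txt, v, max_len)
      expect_equal(length(s$ids), max_len)
      expect_equal(sum(s$ids == 0L), max(0L, max_len - n))
      # pads only in trailing positions
      if (s$n < max_len) expect_true(all(s$ids[(s$n + 1):max_len] == 0L))
    }
  })
})
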