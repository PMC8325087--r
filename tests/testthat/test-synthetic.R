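test_that("word pools are disjoint, stop-word-free, scored, and reproducible", {
  pools <- build_word_pools(seed = 0)
  expect_length(pools$neutral, 500L)
  expect_length(pools$positive, 100L)
  expect_length(pools$negative, 100L)
  expect_length(intersect(pools$positive, pools$negative), 0L)
  expect_length(intersect(pools$neutral, c(pools$positive, pools$negative)), 0L)
  sw <- bundled_stopwords()
  expect_length(intersect(unlist(pools[c("neutral", "positive", "negative")]), sw), 0L)
  expect_true(all(lexicon_score(pools$lexicon, pools$negative) < 0))
  expect_true(all(lexicon_score(pools$lexicon, pools$positive) > 0))
  expect_true(all(lexicon_score(pools$lexicon, pools$neutral) == 0))
  expect_identical(pools, build_word_pools(seed = 0))
})

test_that("invalid corpus specifications are rejected", {
  expect_error(synthetic_corpus_spec(pos_rate_dep = 0.7, neg_rate_dep = 0.5),
               "exceed 1")
  expect_error(synthetic_corpus_spec(pos_rate_dep = -0.1), "rates")
})

test_that("generation is a pure function of the spec", {
  spec <- synthetic_corpus_spec(n_posts = 100, seed = 42)
  s1 <- generate_corpus(spec)
  s2 <- generate_corpus(spec)
  expect_identical(s1$corpus, s2$corpus)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(s1$corpus, f1)
  write_corpus(s2$corpus, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("class counts follow the depression-forum prior", {
  spec <- synthetic_corpus_spec(n_posts = 1842, seed = 0)
  syn <- generate_corpus(spec)
  n_dep <- sum(syn$corpus$label == 1L)
  # 99% binomial interval around the 1293:549 imbalance
  lo <- qbinom(0.005, 1842, 1293 / 1842)
  hi <- qbinom(0.995, 1842, 1293 / 1842)
  expect_gte(n_dep, lo)
  expect_lte(n_dep, hi)
  expect_true(all(lengths(tokenize(syn$corpus$text)) >= 5))
})

test_that("emission rates are recovered from a generated corpus", {
  spec <- synthetic_corpus_spec(n_posts = 5000, seed = 7)
  syn <- generate_corpus(spec)
  tab <- emotion_percentages(syn$corpus, syn$lexicon)
  dep <- tab[tab$label == 1L, ]
  std <- tab[tab$label == 0L, ]
  expect_equal(dep$positive_pct, 8.62, tolerance = 1 / 8.62)   # within 1 pp
  expect_equal(dep$negative_pct, 6.70, tolerance = 1 / 6.70)
  expect_equal(std$positive_pct, 9.41, tolerance = 1 / 9.41)
  expect_equal(std$negative_pct, 4.85, tolerance = 1 / 4.85)
})

test_that("signal strength controls class-exclusive emotion vocabulary", {
  pools <- build_word_pools(seed = 3)
  shared_pos <- pools$positive[1:50]
  shared_neg <- pools$negative[1:50]
  # s = 0: only the shared halves are ever emitted
  syn0 <- generate_corpus(synthetic_corpus_spec(n_posts = 300, seed = 3))
  toks <- unlist(tokenize(syn0$corpus$text))
  emitted_pos <- intersect(toks, pools$positive)
  emitted_neg <- intersect(toks, pools$negative)
  expect_true(all(emitted_pos %in% shared_pos))
  expect_true(all(emitted_neg %in% shared_neg))

  # s = 1: emotion words are fully class-exclusive
  syn1 <- generate_corpus(synthetic_corpus_spec(n_posts = 300, seed = 3,
                                                signal_strength = 1))
  dep_toks <- unlist(tokenize(syn1$corpus$text[syn1$corpus$label == 1L]))
  std_toks <- unlist(tokenize(syn1$corpus$text[syn1$corpus$label == 0L]))
  dep_emo <- intersect(dep_toks, c(pools$positive, pools$negative))
  std_emo <- intersect(std_toks, c(pools$positive, pools$negative))
  expect_length(intersect(dep_emo, std_emo), 0L)
})

test_that("the bundled example posts have the documented labels and split", {
  ex <- example_posts()
  expect_equal(ex$label, c(1L, 1L, 0L))
  sp <- split_by_polarity(tokenize(ex$text[1])[[1]], bundled_lexicon())
  expect_true(all(c("horrible", "die", "stupid") %in% sp$neg_tokens))
  sp2 <- split_by_polarity(tokenize(ex$text[2])[[1]], bundled_lexicon())
  expect_true(all(c("hate", "shitty") %in% sp2$neg_tokens))
})

test_that("stronger identity signal makes the corpus more learnable", {
  lex_cfg <- ean_config(variant = "EAN", units = 16L, dim = 16L, max_len = 90L,
                        max_len_emo = 12L, batch_size = 16L, epochs = 8L,
                        patience = Inf, seed = 0L)
  acc <- vapply(c(0, 0.8), function(s) {
    syn <- generate_corpus(synthetic_corpus_spec(
      n_posts = 300, class_prior = 0.5, signal_strength = s, seed = 5))
    fit <- train_ean(syn$corpus, syn$lexicon, lex_cfg)
    pred <- predict(fit, syn$corpus, syn$lexicon)
    mean(pred$.pred_class == syn$corpus$label)
  }, numeric(1))
  expect_gte(acc[2], acc[1])
  expect_gte(acc[2], 0.9)
})
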