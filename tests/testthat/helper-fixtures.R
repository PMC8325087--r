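# Small in-code fixtures shared across test files.

tiny_corpus <- function() {
  tibble::tibble(
    text = c("i feel horrible and alone today",
             "so tired and sad nothing helps",
             "great day with happy friends",
             "lovely walk and good food"),
    label = c(1L, 1L, 0L, 0L)
  )
}

tiny_lexicon <- function() {
  polarity_lexicon(
    c("horrible", "alone", "tired", "sad", "happy", "good", "great", "lovely"),
    c(-0.8, -0.6, -0.4, -0.7, 0.8, 0.7, 0.8, 0.6)
  )
}

# A linearly separable toy corpus: one word pool per class.
separable_corpus <- function(n_per_class = 20, seed = 1) {
  withr::with_seed(seed, {
    dep <- replicate(n_per_class, paste(sample(c("dark", "empty", "hurt", "sad"),
                                               6, TRUE), collapse = " "))
    std <- replicate(n_per_class, paste(sample(c("sunny", "walk", "coffee", "music"),
                                               6, TRUE), collapse = " "))
    tibble::tibble(text = c(dep, std),
                   label = rep(c(1L, 0L), each = n_per_class))
  })
}

tiny_config <- function(variant = "EAN", ...) {
  defaults <- list(variant = variant, units = 4L, dim = 6L, max_len = 16L,
                   max_len_emo = 6L, batch_size = 8L, epochs = 3L,
                   patience = Inf, val_fraction = 0, seed = 0L)
  args <- utils::modifyList(defaults, list(...))
  do.call(ean_config, args)
}

expect_prob_vector <- function(y) {
  expect_true(all(y >= 0))
  expect_equal(sum(y), 1, tolerance = 1e-6)
}
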