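test_that("lstm_step matches closed forms at zero weights", {
  u <- 3L
  cell <- list(W_i = matrix(0, u + 2, u), W_f = matrix(0, u + 2, u),
               W_c = matrix(0, u + 2, u), W_o = matrix(0, u + 2, u),
               b_i = numeric(u), b_f = numeric(u), b_c = numeric(u),
               b_o = numeric(u), units = u)
  st0 <- list(h = numeric(u), c = numeric(u))
  out <- lstm_step(c(1, -1), st0, cell)
  expect_equal(out$i, rep(0.5, u))
  expect_equal(out$f, rep(0.5, u))
  expect_equal(out$o, rep(0.5, u))
  expect_equal(out$c, numeric(u))
  expect_equal(out$h, numeric(u))

  # with memory c: candidate is tanh(0) = 0, so c' = 0.5 c, h = 0.5 tanh(0.5 c)
  cc <- c(0.4, -1.2, 2)
  out2 <- lstm_step(c(1, -1), list(h = numeric(u), c = cc), cell)
  expect_equal(out2$c, 0.5 * cc)
  expect_equal(out2$h, 0.5 * tanh(0.5 * cc))

  expect_error(lstm_step(c(1, 2, 3), st0, cell), "mismatch")
})

test_that("a multi-step recurrence matches the independent per-step oracle", {
  withr::with_seed(21, {
    d <- 4L; u <- 3L
    cell <- random_cell(d, u)
    xs <- lapply(1:5, function(i) runif(d, -1, 1))
    H <- oracle_lstm(xs, cell)
    st <- list(h = numeric(u), c = numeric(u))
    for (t in 1:5) {
      st <- lstm_step(xs[[t]], st, cell)
      expect_equal(st$h, H[t, ], tolerance = 1e-10)
    }
  })
})

test_that("gate activations stay strictly inside (0, 1)", {
  withr::with_seed(3, {
    d <- 3L; u <- 2L
    for (i in 1:1000) {
      cell <- random_cell(d, u)
      st <- list(h = runif(u, -1, 1), c = runif(u, -2, 2))
      out <- lstm_step(runif(d, -5, 5), st, cell)
      expect_true(all(out$i > 0 & out$i < 1))
      expect_true(all(out$f > 0 & out$f < 1))
      expect_true(all(out$o > 0 & out$o < 1))
    }
  })
})

test_that("bilstm_encode has the contracted shape and palindrome symmetry", {
  v <- build_vocab(tiny_corpus())
  withr::with_seed(5, {
    d <- 4L; u <- 3L
    emb <- matrix(runif(length(v$words) * d, -0.5, 0.5), ncol = d)
    emb[1, ] <- 0
    cell <- random_cell(d, u)

    s1 <- encode_and_pad("alone", v, max_len = 4)
    enc1 <- bilstm_encode(s1, emb, cell, cell)
    expect_equal(dim(enc1$H), c(4L, 2L * u))
    expect_equal(sum(enc1$mask), 1L)
    expect_equal(enc1$H[1, seq_len(u)], enc1$H[1, u + seq_len(u)])

    # palindromic input + tied directions: forward states read left-to-right
    # equal backward states read right-to-left
    s2 <- encode_and_pad("sad day sad", v, max_len = 3)
    enc2 <- bilstm_encode(s2, emb, cell, cell)
    for (t in 1:3) {
      expect_equal(enc2$H[t, seq_len(u)], enc2$H[4 - t, u + seq_len(u)],
                   tolerance = 1e-12)
    }
  })
})

test_that("bilstm_encode agrees with the brute-force oracle on random inputs", {
  withr::with_seed(11, {
    v <- build_vocab(tiny_corpus())
    d <- 5L; u <- 4L
    emb <- matrix(runif(length(v$words) * d, -0.5, 0.5), ncol = d)
    emb[1, ] <- 0
    for (i in 1:20) {
      fwd <- random_cell(d, u); bwd <- random_cell(d, u)
      n <- sample(1:6, 1)
      ids0 <- sample(2:(length(v$words) - 1L), n, replace = TRUE)
      s <- structure(list(ids = c(ids0, rep(0L, 8 - n)), n = n,
                          mask = seq_len(8) <= n, empty = FALSE,
                          tokens = rep("x", 8)), class = "ean_seq")
      enc <- bilstm_encode(s, emb, fwd, bwd)
      expect_equal(enc$H[seq_len(n), , drop = FALSE],
                   oracle_bilstm(ids0, emb, fwd, bwd), tolerance = 1e-5)
    }
  })
})

test_that("attention pooling normalizes, masks, and matches the oracle", {
  withr::with_seed(13, {
    width <- 6L
    # identical rows -> uniform weights, context equals the common row
    att <- random_attention(width)
    row <- runif(width, -1, 1)
    enc <- structure(list(H = rbind(row, row, row, 0),
                          mask = c(TRUE, TRUE, TRUE, FALSE), empty = FALSE),
                     class = "encoded_seq")
    out <- attention_pool(enc, att)
    expect_equal(out$weights, c(rep(1 / 3, 3), 0))
    expect_equal(out$context, row, ignore_attr = TRUE)

    # single unmasked position
    enc1 <- structure(list(H = rbind(row, 0), mask = c(TRUE, FALSE),
                           empty = FALSE), class = "encoded_seq")
    out1 <- attention_pool(enc1, att)
    expect_equal(out1$weights, c(1, 0))
    expect_equal(out1$context, row, ignore_attr = TRUE)

    # random inputs vs brute-force softmax-and-weighted-sum
    for (i in 1:20) {
      n <- sample(2:6, 1)
      H <- matrix(runif(n * width, -1, 1), n, width)
      att <- random_attention(width)
      enc <- structure(list(H = H, mask = rep(TRUE, n), empty = FALSE),
                       class = "encoded_seq")
      out <- attention_pool(enc, att)
      ref <- oracle_attention(H, att$w, att$b, att$q)
      expect_equal(out$weights, ref$alpha, tolerance = 1e-6)
      expect_equal(out$context, ref$context, tolerance = 1e-6)
      expect_equal(sum(out$weights), 1, tolerance = 1e-6)
    }

    # empty side -> zero context
    enc0 <- structure(list(H = matrix(0, 3, width), mask = rep(FALSE, 3),
                           empty = TRUE), class = "encoded_seq")
    out0 <- attention_pool(enc0, random_attention(width))
    expect_equal(out0$context, numeric(width))
    expect_true(out0$empty)
  })
})

test_that("dynamic fusion is the stated convex combination", {
  gate_fixed <- list(mode = "fixed", theta = 0.5)
  v <- c(0.3, -1)
  expect_equal(dynamic_fuse(v, v, gate_fixed)$h_emo, v)

  gate1 <- list(mode = "global", theta_raw = 1e9)   # sigmoid -> 1
  expect_equal(dynamic_fuse(c(1, 0), c(0, 1), gate1)$h_emo, c(1, 0))
  gate0 <- list(mode = "global", theta_raw = -1e9)  # sigmoid -> 0
  expect_equal(dynamic_fuse(c(1, 0), c(0, 1), gate0)$h_emo, c(0, 1))

  # theta = 0.3 directly: h_emo = 0.3 h_pos + 0.7 h_neg
  gate3 <- list(mode = "global", theta_raw = log(0.3 / 0.7))
  out <- dynamic_fuse(c(1, 0), c(0, 1), gate3)
  expect_equal(out$theta, 0.3, tolerance = 1e-12)
  expect_equal(out$h_emo, c(0.3, 0.7), tolerance = 1e-12)

  expect_error(dynamic_fuse(c(1, 2), c(1, 2, 3), gate_fixed), "same length")
})

test_that("forward pass yields a probability vector; zero classifier is uniform", {
  v <- build_vocab(tiny_corpus())
  cfg <- tiny_config()
  m <- build_variant("EAN", cfg, v)
  s <- encode_and_pad(tiny_corpus()$text[1], v, cfg$max_len)
  sp <- encode_split(split_by_polarity(tokenize(tiny_corpus()$text[1])[[1]],
                                       tiny_lexicon()), v, cfg$max_len_emo)
  out <- forward_ean(m, s, sp)
  expect_prob_vector(out$y)
  expect_true(out$diagnostics$theta >= 0 && out$diagnostics$theta <= 1)

  m0 <- m
  m0$params$cls_W[] <- 0
  m0$params$cls_b[] <- 0
  expect_equal(forward_ean(m0, s, sp)$y, c(0.5, 0.5))
})

test_that("appending padding never changes the prediction", {
  v <- build_vocab(tiny_corpus())
  lex <- tiny_lexicon()
  for (len in c(16L, 24L, 40L)) {
    cfg <- tiny_config()
    cfg$max_len <- len
    m <- build_variant("EAN", cfg, v)
    # identical parameters across lengths: rebuild with same seed
    s <- encode_and_pad(tiny_corpus()$text[1], v, len)
    sp <- encode_split(split_by_polarity(tokenize(tiny_corpus()$text[1])[[1]], lex),
                       v, cfg$max_len_emo)
    y <- forward_ean(m, s, sp)$y
    if (len == 16L) y_ref <- y
    expect_equal(y, y_ref, tolerance = 1e-6)
  }
})

test_that("variants have the contracted feature dimensions and gate behavior", {
  v <- build_vocab(tiny_corpus())
  cfg <- tiny_config()
  u <- cfg$units
  expect_equal(build_variant("SUN", cfg, v)$feature_dim, 2L * u)
  expect_equal(build_variant("EUN", cfg, v)$feature_dim, 2L * u)
  expect_equal(build_variant("EAN", cfg, v)$feature_dim, 4L * u)
  expect_equal(build_variant("SUN+positive", cfg, v)$feature_dim, 4L * u)
  expect_equal(build_variant("EAN_concat_fusion", cfg, v)$feature_dim, 6L * u)
  expect_equal(build_variant("LSTM", cfg, v)$units, 128L)
  expect_false(build_variant("BiLSTM", cfg, v)$attention)
  expect_error(build_variant("SUPERNET", cfg, v), "valid names")

  mf <- build_variant("EAN_fixed_fusion", cfg, v)
  out <- dynamic_fuse(runif(2L * u), runif(2L * u), emoattn:::model_gate(mf))
  expect_identical(out$theta, 0.5)
})

test_that("cross-entropy matches its closed forms and clamps zeros", {
  expect_equal(cross_entropy(c(1, 0), 0L), 0)
  expect_equal(cross_entropy(c(0.5, 0.5), 1L), log(2))
  expect_equal(cross_entropy(c(0.9, 0.1), 1L), -log(0.1), tolerance = 1e-12)
  expect_warning(l <- cross_entropy(c(1, 0), 1L), "clamp")
  expect_equal(l, -log(1e-12))
})

test_that("identical seeds give bit-identical models and forward outputs", {
  v <- build_vocab(tiny_corpus())
  cfg <- tiny_config()
  m1 <- build_variant("EAN", cfg, v)
  m2 <- build_variant("EAN", cfg, v)
  expect_identical(m1$params, m2$params)
  s <- encode_and_pad(tiny_corpus()$text[2], v, cfg$max_len)
  sp <- encode_split(split_by_polarity(tokenize(tiny_corpus()$text[2])[[1]],
                                       tiny_lexicon()), v, cfg$max_len_emo)
  expect_identical(forward_ean(m1, s, sp), forward_ean(m2, s, sp))
})
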