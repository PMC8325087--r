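#' Encode a corpus into model-ready index tensors
#'
#' Tokenizes every post, applies the polarity split, and packs ids and
#' lengths into integer matrices (rows = posts, columns = positions; ids are
#' 1-based row indices into the embedding table, padding = row 1). Done once
#' per corpus; minibatches are row slices of these matrices.
#'
#' @param corpus Tibble with `text` and (optionally) `label`.
#' @param vocab An `ean_vocab`.
#' @param lexicon A `polarity_lexicon`, or `NULL` for variants without an
#'   emotion branch.
#' @param max_len,max_len_emo Sequence lengths, as in [ean_config()].
#' @return A list of class `ean_tensors`.
#' @export
encode_corpus <- function(corpus, vocab, lexicon = NULL,
                          max_len = 400L, max_len_emo = 100L) {
  toks <- tokenize(corpus$text)
  n <- length(toks)
  enc_side <- function(token_list, L) {
    len <- pmin(lengths(token_list), L)
    ids <- matrix(PAD_ID + 1L, n, L)
    for (i in seq_len(n)) {
      k <- len[i]
      if (k > 0L) ids[i, seq_len(k)] <- word_ids(vocab, token_list[[i]][seq_len(k)]) + 1L
    }
    list(ids = ids, len = as.integer(len))
  }
  toks <- purrr::map(toks, function(tk) if (length(tk) == 0L) UNK_TOKEN else tk)
  main <- enc_side(toks, max_len)
  out <- list(ids = main$ids, len = main$len, n = n,
              tokens = toks,
              labels = if ("label" %in% names(corpus)) as.integer(corpus$label))
  if (!is.null(lexicon)) {
    scores <- purrr::map(toks, ~ lexicon_score(lexicon, .x))
    pos <- enc_side(purrr::map2(toks, scores, ~ .x[.y > 0]), max_len_emo)
    neg <- enc_side(purrr::map2(toks, scores, ~ .x[.y < 0]), max_len_emo)
    out$pos_ids <- pos$ids; out$pos_len <- pos$len
    out$neg_ids <- neg$ids; out$neg_len <- neg$len
  }
  structure(out, class = "ean_tensors")
}

# Row-slice tensors and trim columns to the longest sequence in the slice
# (at least one column so empty emotion sides keep a well-formed shape).
slice_batch <- function(tensors, rows, model) {
  trim <- function(ids, len) {
    T_eff <- max(1L, max(len[rows]))
    ids_s <- ids[rows, seq_len(T_eff), drop = FALSE]
    m <- matrix(0, length(rows), T_eff)
    for (j in seq_along(rows)) {
      k <- min(len[rows[j]], T_eff)
      if (k > 0L) m[j, seq_len(k)] <- 1
    }
    list(ids = ids_s, mask = m)
  }
  b <- trim(tensors$ids, tensors$len)
  out <- list(ids = b$ids, mask = b$mask,
              labels = if (!is.null(tensors$labels)) tensors$labels[rows])
  if ("pos" %in% model$branches) {
    p <- trim(tensors$pos_ids, tensors$pos_len)
    out$pos_ids <- p$ids; out$pos_mask <- p$mask
  }
  if ("neg" %in% model$branches) {
    q <- trim(tensors$neg_ids, tensors$neg_len)
    out$neg_ids <- q$ids; out$neg_mask <- q$mask
  }
  out
}

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

# Forward a (possibly large) set of rows in evaluation mode, in chunks.
predict_batches <- function(model, tensors, rows = seq_len(tensors$n),
                            chunk = 256L) {
  parts <- split(rows, ceiling(seq_along(rows) / chunk))
  res <- purrr::map(parts, function(r) {
    b <- slice_batch(tensors, r, model)
    f <- ean_forward_batch(model, b)
    list(p = f$p, theta = f$theta, loss = f$loss, n = length(r))
  })
  p <- do.call(rbind, purrr::map(res, "p"))
  loss <- NA_real_
  if (!is.null(tensors$labels)) {
    loss <- sum(purrr::map_dbl(res, ~ .x$loss * .x$n)) / length(rows)
  }
  list(p = p, theta = unlist(purrr::map(res, "theta"), use.names = FALSE),
       loss = loss)
}

#' Train a model on a labeled corpus
#'
#' Minimizes mean cross-entropy with Adam. Every stochastic ingredient
#' (initialization, the held-out split, per-epoch shuffling) is derived from
#' `config$seed`, so identical calls produce bit-identical fits. A stratified
#' fraction of the corpus is held out to drive early stopping on held-out
#' loss; the parameters of the best epoch are kept.
#'
#' @param corpus Tibble with `text` and `label` (both classes present).
#' @param lexicon A `polarity_lexicon` (needed by emotion-branch variants).
#' @param config An [ean_config()].
#' @param vocab Optional pre-built vocabulary (built from `corpus` otherwise).
#' @param embeddings Optional pretrained embedding matrix.
#' @param validation Optional tibble used as the held-out set instead of an
#'   internal split.
#' @param quiet Suppress per-epoch messages.
#' @return An object of class `ean_fit` with the trained `model`, a
#'   `history` tibble (epoch, training loss, held-out loss/accuracy) and the
#'   index of the best epoch.
#' @export
train_ean <- function(corpus, lexicon = NULL, config = ean_config(),
                      vocab = NULL, embeddings = NULL, validation = NULL,
                      quiet = TRUE) {
  stopifnot(nrow(corpus) >= 2L)
  if (length(unique(corpus$label)) < 2L) {
    abort("training requires both classes in the corpus")
  }
  model <- NULL
  needs_lexicon <- any(c("pos", "neg") %in% variant_plan(config$variant)$branches)
  if (needs_lexicon && is.null(lexicon)) {
    abort(paste0("variant ", shQuote(config$variant), " needs a polarity lexicon"))
  }
  if (is.null(vocab)) vocab <- build_vocab(corpus, min_count = config$min_count)
  model <- build_variant(config$variant, config, vocab, embeddings)

  tensors <- encode_corpus(corpus, vocab, if (needs_lexicon) lexicon,
                           config$max_len, config$max_len_emo)

  withr::local_seed(config$seed + 2L)
  n <- tensors$n
  if (!is.null(validation)) {
    val_tensors <- encode_corpus(validation, vocab, if (needs_lexicon) lexicon,
                                 config$max_len, config$max_len_emo)
    train_rows <- seq_len(n)
  } else if (config$val_fraction > 0) {
    val_rows <- stratified_sample(tensors$labels, config$val_fraction)
    train_rows <- setdiff(seq_len(n), val_rows)
    val_tensors <- NULL
  } else {
    train_rows <- seq_len(n)
    val_rows <- integer(0)
    val_tensors <- NULL
  }

  eval_val <- function(m) {
    if (!is.null(validation)) {
      pv <- predict_batches(m, val_tensors)
      labs <- val_tensors$labels
    } else if (length(val_rows) > 0L) {
      pv <- predict_batches(m, tensors, val_rows)
      labs <- tensors$labels[val_rows]
    } else {
      return(c(loss = NA_real_, acc = NA_real_))
    }
    pred <- as.integer(pv$p[, 2] > pv$p[, 1])
    c(loss = pv$loss, acc = mean(pred == labs))
  }

  opt <- adam_init(model$params)
  history <- vector("list", config$epochs)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample(train_rows)
    chunks <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep_loss <- 0
    for (rows in chunks) {
      b <- slice_batch(tensors, rows, model)
      f <- ean_forward_batch(model, b, keep_cache = TRUE)
      g <- ean_backward_batch(model, f, b)
      upd <- adam_update(model$params, g, opt, config$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + f$loss * length(rows)
    }
    ep_loss <- ep_loss / length(perm)
    vm <- eval_val(model)
    history[[epoch]] <- tibble(epoch = epoch, loss = ep_loss,
                               val_loss = vm[["loss"]], val_accuracy = vm[["acc"]])
    if (!quiet) {
      message(sprintf("epoch %d  loss %.4f  val_loss %.4f  val_acc %.4f",
                      epoch, ep_loss, vm[["loss"]], vm[["acc"]]))
    }
    monitor <- if (is.na(vm[["loss"]])) ep_loss else vm[["loss"]]
    if (monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, params = model$params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (is.finite(config$patience) && stall >= config$patience) break
    }
  }
  model$params <- best$params
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         best_epoch = best$epoch, config = config),
    class = "ean_fit"
  )
}

stratified_sample <- function(labels, fraction) {
  idx <- seq_along(labels)
  picked <- lapply(split(idx, labels), function(ii) {
    k <- max(1L, round(length(ii) * fraction))
    sample(ii, k)
  })
  sort(unlist(picked, use.names = FALSE))
}

#' @export
print.ean_fit <- function(x, ...) {
  cat("<ean_fit>", x$model$variant, "- trained", nrow(x$history), "epochs,",
      "best epoch", x$best_epoch, "\n")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final loss %.4f  val_loss %.4f  val_acc %.4f\n",
              last$loss, last$val_loss, last$val_accuracy))
  invisible(x)
}

#' Predict on new posts
#'
#' @param object An `ean_fit`.
#' @param corpus Tibble with a `text` column (a `label` column, if present,
#'   is carried through).
#' @param lexicon Lexicon for the polarity split; defaults to the one used
#'   in training if the caller passes none and the variant needs one.
#' @param ... Unused.
#' @return A tibble with one row per post: predicted class (1 =
#'   depression-indicative), class probabilities, and the realized fusion
#'   gate `theta` (NA for variants without the dynamic gate).
#' @export
predict.ean_fit <- function(object, corpus, lexicon = NULL, ...) {
  model <- object$model
  needs_lexicon <- any(c("pos", "neg") %in% model$branches)
  if (needs_lexicon && is.null(lexicon)) {
    abort("this variant needs the polarity lexicon used at training time")
  }
  tensors <- encode_corpus(corpus, model$vocab, if (needs_lexicon) lexicon,
                           model$max_len, model$max_len_emo)
  pv <- predict_batches(model, tensors)
  out <- tibble(
    .pred_class = as.integer(pv$p[, 2] > pv$p[, 1]),
    .prob_standard = pv$p[, 1],
    .prob_depression = pv$p[, 2],
    theta = pv$theta
  )
  if ("label" %in% names(corpus)) out$label <- as.integer(corpus$label)
  out
}

#' Per-post diagnostics for interpretability reports
#'
#' Runs the model over a corpus and returns, per post, the predicted class,
#' class probabilities, the fusion gate `theta`, and the `top_k` highest
#' attention-weight words of the semantic branch — the raw material for
#' gate-share and attention visualizations.
#'
#' @inheritParams predict.ean_fit
#' @param top_k Number of attention words to keep per post.
#' @return A tibble; `top_words` is a list-column of character vectors.
#' @export
ean_diagnostics <- function(object, corpus, lexicon = NULL, top_k = 5L) {
  model <- object$model
  needs_lexicon <- any(c("pos", "neg") %in% model$branches)
  tensors <- encode_corpus(corpus, model$vocab, if (needs_lexicon) lexicon,
                           model$max_len, model$max_len_emo)
  out <- predict(object, corpus, lexicon)
  top_words <- vector("list", tensors$n)
  if ("sun" %in% model$branches && model$attention) {
    for (start in seq(1L, tensors$n, by = 256L)) {
      rows <- start:min(start + 255L, tensors$n)
      b <- slice_batch(tensors, rows, model)
      f <- ean_forward_batch(model, b)
      for (j in seq_along(rows)) {
        a <- f$alpha_sun[j, ]
        k <- min(top_k, sum(a > 0))
        ord <- order(a, decreasing = TRUE)[seq_len(k)]
        top_words[[rows[j]]] <- tensors$tokens[[rows[j]]][ord]
      }
    }
  }
  out$top_words <- top_words
  out
}

#' Write per-post diagnostics as JSONL
#'
#' @param diagnostics Tibble from [ean_diagnostics()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(diagnostics, path) {
  lines <- vapply(seq_len(nrow(diagnostics)), function(i) {
    rec <- as.list(diagnostics[i, setdiff(names(diagnostics), "top_words")])
    rec$top_words <- diagnostics$top_words[[i]]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
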