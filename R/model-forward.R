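sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell step
#'
#' Applies the standard gated recurrence to a single input vector: with
#' `z = [h_prev; x]`,
#' `i = sigmoid(z W_i + b_i)`, `f = sigmoid(z W_f + b_f)`,
#' `g = tanh(z W_c + b_c)`, `o = sigmoid(z W_o + b_o)`,
#' `c = f * c_prev + i * g`, `h = o * tanh(c)` (all products elementwise).
#'
#' @param x Input vector (length `d`).
#' @param state List with `h` and `c`, each of length `units` (use zero
#'   vectors at the start of a sequence).
#' @param params Cell parameters: `W_i`, `W_f`, `W_c`, `W_o` (each
#'   `(units + d) x units`), biases `b_i`..`b_o`, and `units`.
#' @return List with the new `h`, `c` and the gate activations `i`, `f`, `o`.
#' @export
lstm_step <- function(x, state, params) {
  u <- params$units
  if (length(state$h) != u || length(state$c) != u) {
    abort("state vectors do not match the cell's hidden size")
  }
  z <- c(state$h, x)
  if (length(z) != nrow(params$W_i)) {
    abort(sprintf("input size mismatch: [h; x] has length %d but W_i has %d rows",
                  length(z), nrow(params$W_i)))
  }
  i <- sigmoid(drop(z %*% params$W_i) + params$b_i)
  f <- sigmoid(drop(z %*% params$W_f) + params$b_f)
  g <- tanh(drop(z %*% params$W_c) + params$b_c)
  o <- sigmoid(drop(z %*% params$W_o) + params$b_o)
  c_new <- f * state$c + i * g
  list(h = o * tanh(c_new), c = c_new, i = i, f = f, o = o)
}

#' Encode a sequence with a bidirectional LSTM
#'
#' Runs a forward LSTM left-to-right and a backward LSTM right-to-left over
#' the unmasked (non-padding) positions and concatenates their hidden states
#' per position: `H_t = [h_fwd_t ; h_bwd_t]`. Padding positions get zero rows
#' and are masked out of all downstream pooling.
#'
#' @param seq An `ean_seq` from [encode_and_pad()] or [encode_split()].
#' @param emb Embedding matrix (`V x d`).
#' @param fwd,bwd Cell parameter lists as in [lstm_step()]; pass `bwd = NULL`
#'   for a unidirectional encoder.
#' @return An `encoded_seq`: list with `H` (`max_len x 2u` matrix, or
#'   `max_len x u` if unidirectional), `mask`, and `empty` flag.
#' @export
bilstm_encode <- function(seq, emb, fwd, bwd = NULL) {
  u <- fwd$units
  n <- seq$n
  T_len <- length(seq$ids)
  width <- if (is.null(bwd)) u else 2L * u
  H <- matrix(0, T_len, width)
  if (n > 0L) {
    X <- emb[seq$ids[seq_len(n)] + 1L, , drop = FALSE]
    st <- list(h = numeric(u), c = numeric(u))
    for (t in seq_len(n)) {
      st <- lstm_step(X[t, ], st, fwd)
      H[t, seq_len(u)] <- st$h
    }
    if (!is.null(bwd)) {
      st <- list(h = numeric(u), c = numeric(u))
      for (t in rev(seq_len(n))) {
        st <- lstm_step(X[t, ], st, bwd)
        H[t, u + seq_len(u)] <- st$h
      }
    }
  }
  structure(list(H = H, mask = seq$mask, empty = n == 0L),
            class = "encoded_seq")
}

#' Attention pooling over an encoded sequence
#'
#' Additive attention: each unmasked row is projected through
#' `u_i = tanh(H_i w + b)`, scored against the query `s_i = u_i . q`, the
#' scores pass through a masked softmax, and the context is the weighted sum
#' `sum_i alpha_i H_i`. Padding positions receive exactly zero weight. An
#' empty-flagged input yields a zero context vector (the emotion branch's
#' contract for a post with no words of that polarity).
#'
#' @param enc An `encoded_seq`.
#' @param params Attention parameters: projection `w` (`2u x 2u`), bias `b`,
#'   query `q` (length `2u`).
#' @return An `attention_output`: list with `weights` (length `max_len`,
#'   zeros at masked positions) and `context`.
#' @export
attention_pool <- function(enc, params) {
  T_len <- nrow(enc$H)
  if (isTRUE(enc$empty) || !any(enc$mask)) {
    return(structure(list(weights = numeric(T_len),
                          context = numeric(ncol(enc$H)), empty = TRUE),
                     class = "attention_output"))
  }
  idx <- which(enc$mask)
  Hm <- enc$H[idx, , drop = FALSE]
  U <- tanh(sweep(Hm %*% params$w, 2L, params$b, "+"))
  s <- drop(U %*% params$q)
  e <- exp(s - max(s))
  a <- e / sum(e)
  weights <- numeric(T_len)
  weights[idx] <- a
  context <- drop(crossprod(Hm, a))
  structure(list(weights = weights, context = context, empty = FALSE),
            class = "attention_output")
}

#' Fuse positive and negative emotion contexts
#'
#' The convex gate `h_emo = theta * h_pos + (1 - theta) * h_neg` with
#' `theta` in \[0, 1\] enforced by a sigmoid. In `per_example` mode theta is
#' computed from the pair of contexts (`theta = sigmoid(v . [h_pos; h_neg] + b)`),
#' so each post balances its own positive and negative evidence; in `global`
#' mode one trainable scalar is shared; in `fixed` mode theta is 0.5.
#'
#' @param h_pos,h_neg Context vectors of equal length.
#' @param gate Gate parameters, e.g. from a model's fusion slot:
#'   `list(mode = "per_example", v =, b =)`, `list(mode = "global",
#'   theta_raw =)` or `list(mode = "fixed", theta = 0.5)`.
#' @return List with `h_emo` and the realized `theta`.
#' @export
dynamic_fuse <- function(h_pos, h_neg, gate) {
  if (length(h_pos) != length(h_neg)) {
    abort("h_pos and h_neg must have the same length")
  }
  theta <- switch(gate$mode,
    per_example = sigmoid(sum(gate$v * c(h_pos, h_neg)) + gate$b),
    global = sigmoid(gate$theta_raw),
    fixed = gate$theta,
    abort(paste0("unknown fusion mode ", shQuote(gate$mode)))
  )
  list(h_emo = theta * h_pos + (1 - theta) * h_neg, theta = theta)
}

#' Full forward pass for one post
#'
#' Composes the branches the model's variant prescribes: semantic branch
#' `-> h_att`, emotion branch `-> h_pos, h_neg -> h_emo`, final feature
#' `f_final = [h_att; h_emo]` (or the variant's alternative), and class
#' probabilities `y = softmax(W f_final + b)`. Probability order is
#' `(standard, depression)`, i.e. `y[label + 1]` is the probability of the
#' true class.
#'
#' @param model An `ean_model`.
#' @param seq The encoded full post (`ean_seq`).
#' @param split The encoded polarity split from [encode_split()]; may be
#'   `NULL` for variants without an emotion branch.
#' @return List with `y` (length-2 probability vector) and `diagnostics`
#'   (attention weights per branch and the realized `theta`, where defined).
#' @export
forward_ean <- function(model, seq, split = NULL) {
  feats <- list()
  diag <- list(alpha_sun = NULL, alpha_pos = NULL, alpha_neg = NULL, theta = NA_real_)
  emb <- model$params$emb

  pool <- function(branch, s) {
    enc <- bilstm_encode(s, emb, model_cell(model, branch, "fwd"),
                         if (model$bidirectional) model_cell(model, branch, "bwd"))
    if (model$attention) {
      attention_pool(enc, model_attention(model, branch))
    } else {
      final_state_pool(enc, model$units, model$bidirectional)
    }
  }

  if ("sun" %in% model$branches) {
    att <- pool("sun", seq)
    feats$sun <- att$context
    diag$alpha_sun <- att$weights
  }
  has_pos <- "pos" %in% model$branches
  has_neg <- "neg" %in% model$branches
  if (has_pos) {
    att <- pool("pos", split$pos)
    h_pos <- att$context
    diag$alpha_pos <- att$weights
  }
  if (has_neg) {
    att <- pool("neg", split$neg)
    h_neg <- att$context
    diag$alpha_neg <- att$weights
  }
  if (has_pos && has_neg) {
    if (model$fusion_mode == "concat") {
      feats$emo <- c(h_pos, h_neg)
    } else {
      fused <- dynamic_fuse(h_pos, h_neg, model_gate(model))
      feats$emo <- fused$h_emo
      diag$theta <- fused$theta
    }
  } else if (has_pos) {
    feats$emo <- h_pos
  } else if (has_neg) {
    feats$emo <- h_neg
  }

  f_final <- unlist(feats, use.names = FALSE)
  logits <- drop(f_final %*% model$params$cls_W) + model$params$cls_b
  e <- exp(logits - max(logits))
  list(y = e / sum(e), diagnostics = diag)
}

# Pooling used by the no-attention baselines: last forward state, and (for
# the bidirectional case) the backward state at the first position, i.e. each
# direction's final state.
final_state_pool <- function(enc, u, bidirectional) {
  T_len <- nrow(enc$H)
  if (isTRUE(enc$empty)) {
    return(structure(list(weights = numeric(T_len),
                          context = numeric(ncol(enc$H)), empty = TRUE),
                     class = "attention_output"))
  }
  n <- sum(enc$mask)
  context <- if (bidirectional) {
    c(enc$H[n, seq_len(u)], enc$H[1L, u + seq_len(u)])
  } else {
    enc$H[n, seq_len(u)]
  }
  structure(list(weights = numeric(T_len), context = context, empty = FALSE),
            class = "attention_output")
}

#' Cross-entropy loss
#'
#' `-log y[label]` for a single post; a batch's loss is the mean. A true-class
#' probability of zero is clamped at 1e-12 (with a warning) so the loss stays
#' finite.
#'
#' @param y Length-2 probability vector, order `(standard, depression)`.
#' @param label Class label, 0 or 1.
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(y, label) {
  stopifnot(length(y) == 2L, label %in% c(0L, 1L))
  p <- y[label + 1L]
  if (p <= 0) {
    warn("true-class probability is 0; clamping at 1e-12")
    p <- 1e-12
  }
  -log(p)
}
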