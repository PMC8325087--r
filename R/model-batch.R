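# Batched forward/backward engine.
#
# All training and prediction goes through these internals, which process a
# minibatch per timestep with dense matrix products (BLAS does the heavy
# lifting). Sequences are left-aligned with trailing padding; both LSTM
# directions use the same mask-carry trick: at a padded position the state is
# carried through unchanged, so the forward scan (t = 1..T) ends with each
# row's final state in H[[T]], and the backward scan (t = T..1) produces
# position-aligned outputs without any explicit reversal. Padding positions
# then receive zero attention weight, so they can never influence the output
# (padding invariance is tested).

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Forward scan of one LSTM direction. X: list of T (n x d) inputs; mask:
# n x T numeric 0/1; W packed (u+d) x 4u, gate blocks [i f c o].
lstm_batch_forward <- function(X, mask, W, b, u, reverse = FALSE) {
  T_len <- length(X)
  n <- nrow(X[[1]])
  H <- vector("list", T_len)
  cache <- vector("list", T_len)
  h <- matrix(0, n, u)
  cc <- matrix(0, n, u)
  gi <- seq_len(u); gf <- u + gi; gc <- 2L * u + gi; go <- 3L * u + gi
  order_t <- if (reverse) rev(seq_len(T_len)) else seq_len(T_len)
  for (t in order_t) {
    Z <- add_bias(cbind(h, X[[t]]) %*% W, b)
    i <- sigmoid(Z[, gi, drop = FALSE])
    f <- sigmoid(Z[, gf, drop = FALSE])
    g <- tanh(Z[, gc, drop = FALSE])
    o <- sigmoid(Z[, go, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    m <- mask[, t]
    cache[[t]] <- list(h_prev = h, c_prev = cc, i = i, f = f, g = g, o = o, tc = tc)
    cc <- m * c_new + (1 - m) * cc
    h <- m * h_new + (1 - m) * h
    H[[t]] <- h
  }
  list(H = H, cache = cache)
}

# Backpropagation through one LSTM direction. dH: list of T gradients w.r.t.
# the stored (post-carry) hidden states. Returns packed weight grads and dX.
lstm_batch_backward <- function(dH, fwd, X, mask, W, u) {
  T_len <- length(X)
  n <- nrow(X[[1]])
  d <- ncol(X[[1]])
  dW <- matrix(0, u + d, 4L * u)
  db <- numeric(4L * u)
  dX <- vector("list", T_len)
  dh <- matrix(0, n, u)
  dc <- matrix(0, n, u)
  for (t in rev(fwd$order_t)) {
    cc <- fwd$cache[[t]]
    m <- mask[, t]
    dh_t <- dH[[t]] + dh
    dh_new <- m * dh_t
    dc_new <- m * dc + dh_new * cc$o * (1 - cc$tc^2)
    do_ <- dh_new * cc$tc
    df <- dc_new * cc$c_prev
    di <- dc_new * cc$g
    dg <- dc_new * cc$i
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cbind(cc$h_prev, X[[t]]), dZ)
    db <- db + colSums(dZ)
    dIn <- tcrossprod(dZ, W)
    dh <- (1 - m) * dh_t + dIn[, seq_len(u), drop = FALSE]
    dc <- (1 - m) * dc + dc_new * cc$f
    dX[[t]] <- dIn[, u + seq_len(d), drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

# Batched additive attention with masked softmax. Rows whose mask is all
# zero (empty emotion side) get alpha = 0 everywhere and a zero context.
att_batch_forward <- function(H, mask, w, b, q) {
  T_len <- length(H)
  n <- nrow(H[[1]])
  U <- vector("list", T_len)
  scores <- matrix(-Inf, n, T_len)
  for (t in seq_len(T_len)) {
    U[[t]] <- tanh(add_bias(H[[t]] %*% w, b))
    scores[, t] <- drop(U[[t]] %*% q)
  }
  scores[mask == 0] <- -Inf
  smax <- do.call(pmax, c(as.data.frame(scores), list(na.rm = TRUE)))
  smax[!is.finite(smax)] <- 0
  e <- exp(scores - smax)
  e[mask == 0] <- 0
  z <- rowSums(e)
  alpha <- e / pmax(z, .Machine$double.eps)
  alpha[z == 0, ] <- 0
  ctx <- matrix(0, n, ncol(H[[1]]))
  for (t in seq_len(T_len)) ctx <- ctx + alpha[, t] * H[[t]]
  list(ctx = ctx, alpha = alpha, U = U)
}

att_batch_backward <- function(dctx, att, H, w, q) {
  T_len <- length(H)
  alpha <- att$alpha
  dalpha <- matrix(0, nrow(dctx), T_len)
  dH <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    dalpha[, t] <- rowSums(dctx * H[[t]])
    dH[[t]] <- alpha[, t] * dctx
  }
  ds <- alpha * (dalpha - rowSums(alpha * dalpha))
  dw <- matrix(0, nrow(w), ncol(w))
  db <- numeric(length(q))
  dq <- numeric(length(q))
  for (t in seq_len(T_len)) {
    U <- att$U[[t]]
    dq <- dq + drop(crossprod(U, ds[, t]))
    dpre <- outer(ds[, t], q) * (1 - U^2)
    dw <- dw + crossprod(H[[t]], dpre)
    db <- db + colSums(dpre)
    dH[[t]] <- dH[[t]] + tcrossprod(dpre, w)
  }
  list(dH = dH, dw = dw, db = db, dq = dq)
}

# Encode one branch of a minibatch: embedding lookup, directional scans,
# pooled context. Returns everything the backward pass needs.
ean_branch_forward <- function(model, branch, ids, mask) {
  u <- model$units
  T_len <- ncol(ids)
  emb <- model$params$emb
  X <- lapply(seq_len(T_len), function(t) emb[ids[, t], , drop = FALSE])
  p <- model$params
  fwd <- lstm_batch_forward(X, mask, p[[paste0(branch, "_fwd_W")]],
                            p[[paste0(branch, "_fwd_b")]], u)
  fwd$order_t <- seq_len(T_len)
  out <- list(ids = ids, mask = mask, X = X, fwd = fwd)
  if (model$bidirectional) {
    bwd <- lstm_batch_forward(X, mask, p[[paste0(branch, "_bwd_W")]],
                              p[[paste0(branch, "_bwd_b")]], u, reverse = TRUE)
    bwd$order_t <- rev(seq_len(T_len))
    out$bwd <- bwd
    out$H <- lapply(seq_len(T_len), function(t) cbind(fwd$H[[t]], bwd$H[[t]]))
  } else {
    out$H <- fwd$H
  }
  if (model$attention) {
    out$att <- att_batch_forward(out$H, mask,
                                 p[[paste0(branch, "_att_w")]],
                                 p[[paste0(branch, "_att_b")]],
                                 p[[paste0(branch, "_att_q")]])
    out$ctx <- out$att$ctx
  } else {
    # Final-state pooling: the mask-carry scans leave each row's last real
    # forward state in H[[T]] and last real backward state in H[[1]].
    n <- nrow(ids)
    ctx <- fwd$H[[T_len]]
    if (model$bidirectional) ctx <- cbind(ctx, out$bwd$H[[1L]])
    empty <- rowSums(mask) == 0
    ctx[empty, ] <- 0
    out$ctx <- ctx
  }
  out
}

ean_branch_backward <- function(model, branch, cache, dctx, grads) {
  u <- model$units
  T_len <- length(cache$X)
  p <- model$params
  if (model$attention) {
    ab <- att_batch_backward(dctx, cache$att, cache$H,
                             p[[paste0(branch, "_att_w")]],
                             p[[paste0(branch, "_att_q")]])
    grads[[paste0(branch, "_att_w")]] <- ab$dw
    grads[[paste0(branch, "_att_b")]] <- ab$db
    grads[[paste0(branch, "_att_q")]] <- ab$dq
    dH <- ab$dH
  } else {
    zero <- matrix(0, nrow(dctx), if (model$bidirectional) 2L * u else u)
    empty <- rowSums(cache$mask) == 0
    dctx[empty, ] <- 0
    dH <- rep(list(zero), T_len)
    dH[[T_len]] <- dH[[T_len]] +
      cbind(dctx[, seq_len(u), drop = FALSE],
            matrix(0, nrow(dctx), ncol(zero) - u))
    if (model$bidirectional) {
      dH[[1L]] <- dH[[1L]] +
        cbind(matrix(0, nrow(dctx), u), dctx[, u + seq_len(u), drop = FALSE])
    }
  }
  if (model$bidirectional) {
    dHf <- lapply(dH, function(m) m[, seq_len(u), drop = FALSE])
    dHb <- lapply(dH, function(m) m[, u + seq_len(u), drop = FALSE])
  } else {
    dHf <- dH
  }
  bf <- lstm_batch_backward(dHf, cache$fwd, cache$X, cache$mask,
                            p[[paste0(branch, "_fwd_W")]], u)
  grads[[paste0(branch, "_fwd_W")]] <- bf$dW
  grads[[paste0(branch, "_fwd_b")]] <- bf$db
  dX <- bf$dX
  if (model$bidirectional) {
    bb <- lstm_batch_backward(dHb, cache$bwd, cache$X, cache$mask,
                              p[[paste0(branch, "_bwd_W")]], u)
    grads[[paste0(branch, "_bwd_W")]] <- bb$dW
    grads[[paste0(branch, "_bwd_b")]] <- bb$db
    for (t in seq_len(T_len)) dX[[t]] <- dX[[t]] + bb$dX[[t]]
  }
  # Scatter-add input gradients into the embedding table.
  dX_all <- do.call(rbind, dX)
  ids_vec <- as.vector(cache$ids)
  agg <- rowsum(dX_all, group = ids_vec)
  rows <- as.integer(rownames(agg))
  grads$emb[rows, ] <- grads$emb[rows, ] + agg
  grads
}

# Full forward over a minibatch. `batch` carries 1-based id matrices and
# numeric masks for every branch the variant uses, plus labels.
ean_forward_batch <- function(model, batch, keep_cache = FALSE) {
  n <- nrow(batch$ids)
  caches <- list()
  feats <- list()
  theta <- rep(NA_real_, n)
  has_pos <- "pos" %in% model$branches
  has_neg <- "neg" %in% model$branches

  if ("sun" %in% model$branches) {
    caches$sun <- ean_branch_forward(model, "sun", batch$ids, batch$mask)
    feats$sun <- caches$sun$ctx
  }
  if (has_pos) {
    caches$pos <- ean_branch_forward(model, "pos", batch$pos_ids, batch$pos_mask)
  }
  if (has_neg) {
    caches$neg <- ean_branch_forward(model, "neg", batch$neg_ids, batch$neg_mask)
  }
  fus <- NULL
  if (has_pos && has_neg) {
    Hp <- caches$pos$ctx
    Hn <- caches$neg$ctx
    if (model$fusion_mode == "concat") {
      feats$emo <- cbind(Hp, Hn)
    } else if (model$fusion_mode == "per_example") {
      z <- drop(cbind(Hp, Hn) %*% model$params$fus_v) + model$params$fus_b
      theta <- sigmoid(z)
      feats$emo <- theta * Hp + (1 - theta) * Hn
      fus <- list(Hp = Hp, Hn = Hn, theta = theta)
    } else if (model$fusion_mode == "global") {
      th <- sigmoid(model$params$fus_theta)
      theta <- rep(th, n)
      feats$emo <- th * Hp + (1 - th) * Hn
      fus <- list(Hp = Hp, Hn = Hn, theta = theta)
    } else {  # fixed
      theta <- rep(0.5, n)
      feats$emo <- 0.5 * Hp + 0.5 * Hn
      fus <- list(Hp = Hp, Hn = Hn, theta = theta)
    }
  } else if (has_pos) {
    feats$emo <- caches$pos$ctx
  } else if (has_neg) {
    feats$emo <- caches$neg$ctx
  }

  Fmat <- do.call(cbind, feats)
  logits <- add_bias(Fmat %*% model$params$cls_W, model$params$cls_b)
  m <- pmax(logits[, 1], logits[, 2])
  e <- exp(logits - m)
  p <- e / rowSums(e)

  out <- list(p = p, theta = theta,
              alpha_sun = if (!is.null(caches$sun$att)) caches$sun$att$alpha)
  if (!is.null(batch$labels)) {
    truth <- pmax(p[cbind(seq_len(n), batch$labels + 1L)], 1e-12)
    out$loss <- -mean(log(truth))
  }
  if (keep_cache) {
    out$caches <- caches
    out$feats <- feats
    out$Fmat <- Fmat
    out$fus <- fus
  }
  out
}

ean_backward_batch <- function(model, fwd, batch) {
  n <- nrow(batch$ids)
  p <- fwd$p
  Y <- matrix(0, n, 2L)
  Y[cbind(seq_len(n), batch$labels + 1L)] <- 1
  dlogits <- (p - Y) / n

  grads <- list(emb = matrix(0, nrow(model$params$emb), ncol(model$params$emb)))
  grads$cls_W <- crossprod(fwd$Fmat, dlogits)
  grads$cls_b <- colSums(dlogits)
  dF <- tcrossprod(dlogits, model$params$cls_W)

  off <- 0L
  take <- function(k) {
    cols <- off + seq_len(k)
    off <<- off + k
    dF[, cols, drop = FALSE]
  }
  ctx_dim <- model$ctx_dim
  has_pos <- "pos" %in% model$branches
  has_neg <- "neg" %in% model$branches

  if ("sun" %in% model$branches) {
    d_sun <- take(ctx_dim)
    grads <- ean_branch_backward(model, "sun", fwd$caches$sun, d_sun, grads)
  }
  if (has_pos && has_neg) {
    if (model$fusion_mode == "concat") {
      dHp <- take(ctx_dim)
      dHn <- take(ctx_dim)
    } else {
      d_emo <- take(ctx_dim)
      fus <- fwd$fus
      theta <- fus$theta
      dHp <- theta * d_emo
      dHn <- (1 - theta) * d_emo
      dtheta <- rowSums(d_emo * (fus$Hp - fus$Hn))
      if (model$fusion_mode == "per_example") {
        dz <- dtheta * theta * (1 - theta)
        grads$fus_v <- drop(crossprod(cbind(fus$Hp, fus$Hn), dz))
        grads$fus_b <- sum(dz)
        dHpHn <- outer(dz, model$params$fus_v)
        dHp <- dHp + dHpHn[, seq_len(ctx_dim), drop = FALSE]
        dHn <- dHn + dHpHn[, ctx_dim + seq_len(ctx_dim), drop = FALSE]
      } else if (model$fusion_mode == "global") {
        th <- theta[1]
        grads$fus_theta <- sum(dtheta) * th * (1 - th)
      }
    }
    grads <- ean_branch_backward(model, "pos", fwd$caches$pos, dHp, grads)
    grads <- ean_branch_backward(model, "neg", fwd$caches$neg, dHn, grads)
  } else if (has_pos) {
    grads <- ean_branch_backward(model, "pos", fwd$caches$pos, take(ctx_dim), grads)
  } else if (has_neg) {
    grads <- ean_branch_backward(model, "neg", fwd$caches$neg, take(ctx_dim), grads)
  }
  # Padding embedding stays frozen at zero.
  grads$emb[PAD_ID + 1L, ] <- 0
  grads
}
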