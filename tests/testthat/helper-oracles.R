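# Independent brute-force reference implementations. These deliberately share
# no code with the package: plain loops, per-gate matrices, no masking tricks.

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# Per-step LSTM recurrence over a plain list of input vectors.
oracle_lstm <- function(xs, cell) {
  u <- cell$units
  h <- numeric(u)
  cc <- numeric(u)
  H <- matrix(0, length(xs), u)
  for (t in seq_along(xs)) {
    z <- c(h, xs[[t]])
    i <- oracle_sigmoid(drop(z %*% cell$W_i) + cell$b_i)
    f <- oracle_sigmoid(drop(z %*% cell$W_f) + cell$b_f)
    g <- tanh(drop(z %*% cell$W_c) + cell$b_c)
    o <- oracle_sigmoid(drop(z %*% cell$W_o) + cell$b_o)
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    H[t, ] <- h
  }
  H
}

# Bi-directional encoding of an id sequence: forward over 1..n, backward over
# n..1, concatenated per position.
oracle_bilstm <- function(ids0, emb, fwd, bwd) {
  xs <- lapply(ids0 + 1L, function(r) emb[r, ])
  Hf <- oracle_lstm(xs, fwd)
  Hb <- oracle_lstm(rev(xs), bwd)
  cbind(Hf, Hb[rev(seq_along(xs)), , drop = FALSE])
}

# Additive attention over the rows of H (all rows valid).
oracle_attention <- function(H, w, b, q) {
  n <- nrow(H)
  s <- numeric(n)
  U <- matrix(0, n, ncol(H))
  for (i in seq_len(n)) {
    U[i, ] <- tanh(drop(H[i, ] %*% w) + b)
    s[i] <- sum(U[i, ] * q)
  }
  a <- exp(s - max(s))
  a <- a / sum(a)
  list(alpha = a, context = drop(t(H) %*% a))
}

oracle_metrics <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(accuracy = (tp + tn) / total,
    precision = p,
    recall = r,
    f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

# Random cell parameters in the per-gate layout the public API uses.
random_cell <- function(input_dim, units) {
  rmat <- function(nr, nc) matrix(runif(nr * nc, -0.4, 0.4), nr, nc)
  list(W_i = rmat(units + input_dim, units),
       W_f = rmat(units + input_dim, units),
       W_c = rmat(units + input_dim, units),
       W_o = rmat(units + input_dim, units),
       b_i = runif(units, -0.1, 0.1),
       b_f = runif(units, -0.1, 0.1),
       b_c = runif(units, -0.1, 0.1),
       b_o = runif(units, -0.1, 0.1),
       units = units)
}

random_attention <- function(width) {
  list(w = matrix(runif(width * width, -0.4, 0.4), width, width),
       b = runif(width, -0.1, 0.1),
       q = runif(width, -0.4, 0.4))
}
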