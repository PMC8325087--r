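#' Model and training configuration
#'
#' Collects every tunable of the classifier and its trainer in one list.
#' Defaults follow the published setting where one exists (Bi-LSTM unit size
#' 64, single-direction LSTM baseline unit size 128, Adam, batch size 128);
#' the remaining knobs (learning rate, epoch budget, early stopping, sequence
#' lengths) are documented package defaults.
#'
#' @param variant Architecture name, see [build_variant()].
#' @param units Hidden size `u` of each LSTM direction (the LSTM baseline
#'   overrides this with 128).
#' @param dim Word-embedding dimension (300 matches pretrained GloVe; smaller
#'   values are sensible for synthetic vocabularies).
#' @param max_len Sequence length for the full post.
#' @param max_len_emo Sequence length for each emotional sub-sequence.
#' @param fusion `"per_example"` (gate computed from `[h_pos; h_neg]` per
#'   post) or `"global"` (one trainable scalar); ignored by the fixed- and
#'   concatenate-fusion variants.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience, in epochs without improvement of
#'   held-out loss; `Inf` disables early stopping.
#' @param val_fraction Fraction of the training split held out for early
#'   stopping (stratified).
#' @param min_count Vocabulary frequency cutoff.
#' @param seed Integer seed driving initialization, shuffling and splits.
#' @return A list of class `ean_config`.
#' @export
ean_config <- function(variant = "EAN",
                       units = 64L,
                       dim = 300L,
                       max_len = 400L,
                       max_len_emo = 100L,
                       fusion = c("per_example", "global"),
                       batch_size = 128L,
                       learning_rate = 1e-3,
                       epochs = 20L,
                       patience = 3L,
                       val_fraction = 0.1,
                       min_count = 1L,
                       seed = 0L) {
  fusion <- match.arg(fusion)
  stopifnot(units >= 1, dim >= 1, max_len >= 1, max_len_emo >= 1,
            batch_size >= 1, learning_rate >= 0, epochs >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(
    list(variant = variant, units = as.integer(units), dim = as.integer(dim),
         max_len = as.integer(max_len), max_len_emo = as.integer(max_len_emo),
         fusion = fusion, batch_size = as.integer(batch_size),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         patience = patience, val_fraction = val_fraction,
         min_count = as.integer(min_count), seed = as.integer(seed)),
    class = "ean_config"
  )
}

#' Architecture variants
#'
#' @return Character vector of recognised variant names.
#' @export
ean_variants <- function() {
  c("EAN", "SUN", "EUN", "SUN+positive", "SUN+negative",
    "LSTM", "BiLSTM", "BiLSTM+Att", "EAN_fixed_fusion", "EAN_concat_fusion")
}

variant_plan <- function(name) {
  switch(name,
    "EAN"               = list(branches = c("sun", "pos", "neg"), fusion = "dynamic"),
    "EAN_fixed_fusion"  = list(branches = c("sun", "pos", "neg"), fusion = "fixed"),
    "EAN_concat_fusion" = list(branches = c("sun", "pos", "neg"), fusion = "concat"),
    "SUN"               = list(branches = "sun", fusion = "none"),
    "BiLSTM+Att"        = list(branches = "sun", fusion = "none"),
    "EUN"               = list(branches = c("pos", "neg"), fusion = "dynamic"),
    "SUN+positive"      = list(branches = c("sun", "pos"), fusion = "none"),
    "SUN+negative"      = list(branches = c("sun", "neg"), fusion = "none"),
    "LSTM"              = list(branches = "sun", fusion = "none",
                               bidirectional = FALSE, attention = FALSE, units = 128L),
    "BiLSTM"            = list(branches = "sun", fusion = "none", attention = FALSE),
    abort(paste0("unknown variant ", shQuote(name), "; valid names: ",
                 paste(ean_variants(), collapse = ", ")))
  )
}

#' Build a model variant
#'
#' Constructs an initialized (untrained) network of the requested
#' architecture. `"EAN"` is the full two-branch model: a semantic branch
#' (Bi-LSTM + attention over the whole post, output `h_att`) and an emotion
#' branch (twin Bi-LSTM + attention encoders over the positive and negative
#' word sub-sequences, outputs `h_pos` and `h_neg`, fused to
#' `h_emo = theta * h_pos + (1 - theta) * h_neg`). Ablations drop or alter
#' parts of it:
#'
#' * `"SUN"` (alias `"BiLSTM+Att"`): semantic branch only.
#' * `"EUN"`: emotion branch only.
#' * `"SUN+positive"` / `"SUN+negative"`: semantic branch plus a single
#'   emotion unit, concatenated without fusion.
#' * `"EAN_fixed_fusion"`: gate pinned at `theta = 0.5`.
#' * `"EAN_concat_fusion"`: `[h_pos; h_neg]` concatenated instead of fused.
#' * `"LSTM"` / `"BiLSTM"`: single-branch baselines without attention
#'   (final-state pooling; the unidirectional baseline uses 128 units).
#'
#' All weights are initialized uniformly in (-0.05, 0.05) from
#' `config$seed`; biases start at zero.
#'
#' @param name A variant name from [ean_variants()].
#' @param config An [ean_config()].
#' @param vocab An `ean_vocab`.
#' @param embeddings Optional `V x dim` embedding matrix from
#'   [load_embeddings()]; by default a seeded random matrix.
#' @return An object of class `ean_model`.
#' @export
build_variant <- function(name, config = ean_config(), vocab, embeddings = NULL) {
  plan <- variant_plan(name)
  u <- plan$units %||% config$units
  bidir <- plan$bidirectional %||% TRUE
  attn <- plan$attention %||% TRUE
  d <- config$dim
  if (is.null(embeddings)) {
    embeddings <- load_embeddings(NULL, vocab, d, seed = config$seed)
  }
  stopifnot(nrow(embeddings) == length(vocab$words), ncol(embeddings) == d)
  ctx_dim <- if (bidir) 2L * u else u
  fusion_mode <- if (plan$fusion == "dynamic") config$fusion else plan$fusion

  feature_dim <- 0L
  if ("sun" %in% plan$branches) feature_dim <- feature_dim + ctx_dim
  emo_units <- intersect(c("pos", "neg"), plan$branches)
  if (length(emo_units) > 0L) {
    feature_dim <- feature_dim +
      if (fusion_mode == "concat") 2L * ctx_dim else ctx_dim
  }

  params <- withr::with_seed(config$seed + 1L, {
    p <- list(emb = embeddings)
    for (br in plan$branches) {
      p[[paste0(br, "_fwd_W")]] <- init_mat(u + d, 4L * u)
      p[[paste0(br, "_fwd_b")]] <- numeric(4L * u)
      if (bidir) {
        p[[paste0(br, "_bwd_W")]] <- init_mat(u + d, 4L * u)
        p[[paste0(br, "_bwd_b")]] <- numeric(4L * u)
      }
      if (attn) {
        p[[paste0(br, "_att_w")]] <- init_mat(ctx_dim, ctx_dim)
        p[[paste0(br, "_att_b")]] <- numeric(ctx_dim)
        p[[paste0(br, "_att_q")]] <- init_mat(ctx_dim, 1L)[, 1]
      }
    }
    if (length(emo_units) == 2L) {
      if (fusion_mode == "per_example") {
        p$fus_v <- init_mat(2L * ctx_dim, 1L)[, 1]
        p$fus_b <- 0
      } else if (fusion_mode == "global") {
        p$fus_theta <- 0  # sigmoid(0) = 0.5 at start
      }
    }
    p$cls_W <- init_mat(feature_dim, 2L)
    p$cls_b <- numeric(2L)
    p
  })

  structure(
    list(variant = name, units = u, dim = d, ctx_dim = ctx_dim,
         branches = plan$branches, bidirectional = bidir, attention = attn,
         fusion_mode = fusion_mode, feature_dim = feature_dim,
         max_len = config$max_len, max_len_emo = config$max_len_emo,
         vocab = vocab, params = params, config = config),
    class = "ean_model"
  )
}

init_mat <- function(nr, nc) matrix(runif(nr * nc, -0.05, 0.05), nr, nc)

#' @export
print.ean_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<ean_model>", x$variant,
      sprintf("(u=%d, d=%d, fusion=%s, %s params)\n",
              x$units, x$dim, x$fusion_mode, format(np, big.mark = ",")))
  cat("  branches:", paste(x$branches, collapse = " + "),
      "| feature dim:", x$feature_dim, "\n")
  invisible(x)
}

# Split the packed (u+d) x 4u gate matrix into the per-gate view used by the
# single-step API. Column blocks are input, forget, candidate, output.
unpack_cell <- function(W, b, u) {
  g <- function(k) ((k - 1L) * u + 1L):(k * u)
  list(W_i = W[, g(1)], W_f = W[, g(2)], W_c = W[, g(3)], W_o = W[, g(4)],
       b_i = b[g(1)], b_f = b[g(2)], b_c = b[g(3)], b_o = b[g(4)], units = u)
}

model_cell <- function(model, branch, dir) {
  W <- model$params[[paste0(branch, "_", dir, "_W")]]
  b <- model$params[[paste0(branch, "_", dir, "_b")]]
  unpack_cell(W, b, model$units)
}

model_attention <- function(model, branch) {
  list(w = model$params[[paste0(branch, "_att_w")]],
       b = model$params[[paste0(branch, "_att_b")]],
       q = model$params[[paste0(branch, "_att_q")]])
}

model_gate <- function(model) {
  switch(model$fusion_mode,
    per_example = list(mode = "per_example", v = model$params$fus_v,
                       b = model$params$fus_b),
    global = list(mode = "global", theta_raw = model$params$fus_theta),
    fixed = list(mode = "fixed", theta = 0.5),
    abort(paste0("variant ", shQuote(model$variant), " has no fusion gate"))
  )
}
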