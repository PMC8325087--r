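# Curated high-frequency emotion words of depression-forum language, used to
# seed the generator's word pools and the bundled demo lexicon.
box1_positive <- c(
  "friends", "good", "work", "help", "better", "happy", "job", "love", "hard",
  "friend", "family", "care", "wanted", "best", "sleep", "sure", "mind",
  "understand", "hope", "social", "money", "remember", "working", "reason",
  "okay", "close", "real", "together", "great", "normal", "deal", "believe",
  "change", "enjoy", "birthday", "honestly", "nice", "motivation", "advice",
  "loved", "therapist", "happiness", "fun", "boyfriend", "big", "sister",
  "friendship", "brother", "father", "kids", "child", "baby", "married",
  "conversation", "spend"
)

box1_negative <- c(
  "depression", "depressed", "bad", "fucking", "alone", "hate", "shit",
  "lost", "worse", "anxiety", "fuck", "tired", "sad", "die", "suicide",
  "kill", "wrong", "pain", "suicidal", "problems", "sorry", "cry", "lonely",
  "therapy", "hurt", "stupid", "constantly", "issues", "sick", "crying",
  "problem", "afraid", "weird", "hospital", "worst", "illness", "dead",
  "scared", "dark", "broken", "shitty", "broke", "miserable", "died", "cut",
  "angry", "upset", "annoyed", "hell", "cancer", "toxic", "fault",
  "horrible", "awkward", "selfish", "confused", "difficult"
)

#' Specification of a synthetic labeled corpus
#'
#' Describes the generative process the package uses to emulate the lexical
#' statistics of a depression-forum corpus: a Bernoulli class label (default
#' prior 1293/1842, the published corpus' imbalance), a truncated-Poisson
#' post length, and per-token emission of positive-pool, negative-pool or
#' neutral-pool words at class-conditional rates. Default rates match the
#' published per-class emotion-word percentages (depression class: 8.62%
#' positive, 6.70% negative; standard class: 9.41% and 4.85%).
#'
#' `signal_strength` controls how much emotion-word *identity* (not just
#' rate) carries the label: a fraction `s` of emotion-word draws comes from a
#' class-exclusive half of the pool. At `s = 0` the classes differ only in
#' rates; at `s = 1` the emotional vocabulary is fully class-specific.
#' `signal_pos` / `signal_neg` override `s` per pool, e.g. to build corpora
#' where only negative vocabulary is informative.
#'
#' @param n_posts Number of posts.
#' @param class_prior P(depression-indicative).
#' @param pos_rate_dep,neg_rate_dep,pos_rate_std,neg_rate_std Per-class
#'   per-token emission probabilities of positive/negative emotion words.
#' @param signal_strength Identity signal s in \[0, 1\].
#' @param signal_pos,signal_neg Per-pool overrides of `signal_strength`.
#' @param mean_length Poisson mean of post length (tokens).
#' @param min_length Lower truncation of post length.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A list of class `synthetic_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(n_posts = 1842L,
                                  class_prior = 1293 / 1842,
                                  pos_rate_dep = 0.0862,
                                  neg_rate_dep = 0.0670,
                                  pos_rate_std = 0.0941,
                                  neg_rate_std = 0.0485,
                                  signal_strength = 0,
                                  signal_pos = signal_strength,
                                  signal_neg = signal_strength,
                                  mean_length = 60,
                                  min_length = 5L,
                                  seed = 0L) {
  rates <- c(pos_rate_dep, neg_rate_dep, pos_rate_std, neg_rate_std)
  if (any(rates < 0 | rates > 1)) abort("emotion-word rates must lie in [0, 1]")
  if (pos_rate_dep + neg_rate_dep > 1 || pos_rate_std + neg_rate_std > 1) {
    abort("within each class, pos_rate + neg_rate must not exceed 1")
  }
  stopifnot(n_posts >= 1, class_prior >= 0, class_prior <= 1,
            signal_pos >= 0, signal_pos <= 1, signal_neg >= 0, signal_neg <= 1,
            mean_length > 0, min_length >= 1)
  structure(
    list(n_posts = as.integer(n_posts), class_prior = class_prior,
         pos_rate_dep = pos_rate_dep, neg_rate_dep = neg_rate_dep,
         pos_rate_std = pos_rate_std, neg_rate_std = neg_rate_std,
         signal_strength = signal_strength,
         signal_pos = signal_pos, signal_neg = signal_neg,
         mean_length = mean_length, min_length = as.integer(min_length),
         seed = as.integer(seed)),
    class = "synthetic_corpus_spec"
  )
}

# Pronounceable pseudo-words, deterministically generated, guaranteed not to
# collide with `avoid`.
make_pseudo_words <- function(n, avoid = character(0)) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out)
    syll <- function(m) paste0(sample(consonants, m, TRUE), sample(vowels, m, TRUE))
    words <- vapply(sample(2:4, k, TRUE), function(ns) {
      paste(vapply(seq_len(ns), function(i) syll(1L), character(1)), collapse = "")
    }, character(1))
    out <- unique(c(out, setdiff(words, avoid)))
  }
  out[seq_len(n)]
}

#' Build the generator's word pools
#'
#' Three pairwise-disjoint pools: 500 neutral, 100 positive and 100 negative
#' words. The emotion pools start from curated depression-forum emotion
#' words (filtered against the bundled stop-word list, so corpus statistics
#' computed after stop-word removal recover the generator's rates exactly)
#' and are topped up with pseudo-words; the neutral pool is fully synthetic.
#' The matching lexicon scores +0.5 / -0.5 / absent by pool.
#'
#' @param seed Integer seed.
#' @param n_neutral,n_positive,n_negative Pool sizes.
#' @return List with `neutral`, `positive`, `negative` (character vectors)
#'   and `lexicon` (a `polarity_lexicon`).
#' @export
build_word_pools <- function(seed = 0L, n_neutral = 500L,
                             n_positive = 100L, n_negative = 100L) {
  stop_list <- bundled_stopwords()
  pos_base <- setdiff(unique(box1_positive), stop_list)
  neg_base <- setdiff(setdiff(unique(box1_negative), stop_list), pos_base)
  withr::with_seed(seed, {
    avoid <- c(pos_base, neg_base, stop_list)
    extra <- make_pseudo_words(
      n_neutral + max(0L, n_positive - length(pos_base)) +
        max(0L, n_negative - length(neg_base)),
      avoid = avoid
    )
    need_pos <- max(0L, n_positive - length(pos_base))
    need_neg <- max(0L, n_negative - length(neg_base))
    positive <- c(pos_base[seq_len(min(n_positive, length(pos_base)))],
                  extra[seq_len(need_pos)])
    negative <- c(neg_base[seq_len(min(n_negative, length(neg_base)))],
                  extra[need_pos + seq_len(need_neg)])
    neutral <- extra[need_pos + need_neg + seq_len(n_neutral)]
    lex <- polarity_lexicon(
      c(positive, negative),
      c(rep(0.5, length(positive)), rep(-0.5, length(negative))),
      name = sprintf("synthetic-pools-seed%d", seed)
    )
    list(neutral = neutral, positive = positive, negative = negative,
         lexicon = lex)
  })
}

#' Generate a synthetic labeled corpus
#'
#' Draws a corpus from a [synthetic_corpus_spec()]: per post a class label
#' from the prior and a truncated-Poisson length; per token a pool (positive
#' / negative / neutral) at the class's rates; within an emotion pool, a
#' class-exclusive sub-pool with the pool's signal probability, the shared
#' sub-pool otherwise. Identical specs yield identical corpora.
#'
#' @param spec A `synthetic_corpus_spec`.
#' @return A list of class `synthetic_corpus` with `corpus` (tibble
#'   `text`/`label`), `lexicon` (the pools' `polarity_lexicon`), `pools`,
#'   and the `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_corpus_spec"))
  pools <- build_word_pools(spec$seed)
  half <- function(pool) {
    k <- length(pool)
    list(shared = pool[seq_len(k %/% 2)],
         dep = pool[(k %/% 2 + 1):(k %/% 2 + ceiling(k / 4))],
         std = pool[(k %/% 2 + ceiling(k / 4) + 1):k])
  }
  pp <- half(pools$positive)
  np <- half(pools$negative)
  withr::with_seed(spec$seed + 1L, {
    n <- spec$n_posts
    label <- rbinom(n, 1L, spec$class_prior)
    len <- rpois(n, spec$mean_length)
    len[len < spec$min_length] <- spec$min_length
    N <- sum(len)
    tok_label <- rep(label, len)
    pos_rate <- ifelse(tok_label == 1L, spec$pos_rate_dep, spec$pos_rate_std)
    neg_rate <- ifelse(tok_label == 1L, spec$neg_rate_dep, spec$neg_rate_std)
    u <- runif(N)
    cat_pos <- u < pos_rate
    cat_neg <- !cat_pos & u < pos_rate + neg_rate
    words <- character(N)
    draw_pool <- function(is_cat, sub, signal) {
      idx <- which(is_cat)
      if (length(idx) == 0L) return()
      excl <- runif(length(idx)) < signal
      cls <- tok_label[idx]
      src <- ifelse(excl, ifelse(cls == 1L, "dep", "std"), "shared")
      for (s in c("shared", "dep", "std")) {
        sel <- idx[src == s]
        if (length(sel) > 0L) {
          words[sel] <<- sample(sub[[s]], length(sel), replace = TRUE)
        }
      }
    }
    draw_pool(cat_pos, pp, spec$signal_pos)
    draw_pool(cat_neg, np, spec$signal_neg)
    neu <- which(!cat_pos & !cat_neg)
    words[neu] <- sample(pools$neutral, length(neu), replace = TRUE)
    post_id <- rep(seq_len(n), len)
    text <- vapply(split(words, post_id), paste, character(1), collapse = " ")
    structure(
      list(corpus = tibble(text = unname(text), label = label),
           lexicon = pools$lexicon, pools = pools, spec = spec),
      class = "synthetic_corpus"
    )
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus>", nrow(x$corpus), "posts,",
      sum(x$corpus$label == 1L), "depression-indicative /",
      sum(x$corpus$label == 0L), "standard\n")
  invisible(x)
}

#' Bundled illustrative posts
#'
#' Three short forum posts (two depression-indicative, one standard) used in
#' examples and smoke tests: the depression-indicative posts carry strongly
#' negative emotion words (horrible, die, stupid; hate, shitty), the standard
#' post does not.
#'
#' @return A tibble with `text` and `label` (1, 1, 0).
#' @export
example_posts <- function() {
  tibble(
    text = c(
      paste("Today, I feel so horrible, it makes me want to die I made a fool",
            "of myself at work, felt so stupid after the meeting so I left work,",
            "told the boss I'm sick. Spent the remaining afternoon in bed."),
      paste("That feeling when you hate who you are as a person but can't get",
            "yourself to change because you are so used to being like this for",
            "the past several years. I've become a shitty person. The thought",
            "of change seems impossible to me at this point."),
      "Looking for cool ways to tell parents my wife is pregnant."
    ),
    label = c(1L, 1L, 0L)
  )
}
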