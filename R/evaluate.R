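#' Classification metrics from confusion counts
#'
#' The depression-indicative class is the positive class. Definitions:
#' accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' and F1 the harmonic mean `2PR/(P+R)`. Any division by zero yields 0 with
#' a warning.
#'
#' @param counts Named list or vector with `tp`, `fp`, `fn`, `tn`.
#' @return A one-row tibble with `accuracy`, `precision`, `recall`, `f1`
#'   (each in \[0, 1\]) and the counts.
#' @examples
#' compute_metrics(c(tp = 3, fp = 1, fn = 1, tn = 5))
#' @export
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  total <- tp + fp + fn + tn
  if (total == 0) abort("empty confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, ": denominator is 0; reporting 0"))
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(accuracy = (tp + tn) / total, precision = precision,
         recall = recall, f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn)
}

confusion_counts <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate))
  list(tp = sum(truth == 1 & estimate == 1),
       fp = sum(truth == 0 & estimate == 1),
       fn = sum(truth == 1 & estimate == 0),
       tn = sum(truth == 0 & estimate == 0))
}

#' Stratified fold assignment
#'
#' Assigns each post to one of `k` folds such that every fold's class ratio
#' matches the corpus ratio to within one post per class. Deterministic given
#' `seed`.
#'
#' @param labels Integer class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, same length as `labels`.
#' @export
stratified_folds <- function(labels, k, seed = 0L) {
  tab <- table(labels)
  if (any(tab < k)) {
    abort(paste0("smallest class has ", min(tab), " posts; need at least ", k,
                 " per class for ", k, " folds - use fewer folds"))
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in names(tab)) {
      idx <- sample(which(labels == as.integer(cls)))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Trains the configured variant on 9/10 of the corpus and evaluates on the
#' remaining 1/10, rotating so each post is tested exactly once, with folds
#' stratified by class. Each fold's model is freshly initialized from a seed
#' derived from `config$seed` and the fold index, so whole runs are
#' reproducible bit-for-bit.
#'
#' @param corpus Tibble with `text` and `label`.
#' @param lexicon A `polarity_lexicon` (for emotion-branch variants).
#' @param config An [ean_config()].
#' @param folds Number of folds (default 10).
#' @param diagnostics If `TRUE`, collect each test post's fusion gate `theta`
#'   (used by the gate-share report).
#' @param quiet Suppress progress messages.
#' @return An object of class `ean_cv`: per-fold metrics, their mean and
#'   standard deviation, and optionally per-post diagnostics.
#' @export
cross_validate <- function(corpus, lexicon = NULL, config = ean_config(),
                           folds = 10L, diagnostics = FALSE, quiet = TRUE) {
  labels <- as.integer(corpus$label)
  fold <- stratified_folds(labels, folds, seed = config$seed)
  per_fold <- vector("list", folds)
  diag_rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    cfg <- config
    cfg$seed <- config$seed + 1000L * f
    fit <- train_ean(corpus[train_idx, ], lexicon, cfg, quiet = TRUE)
    pred <- predict(fit, corpus[test_idx, ], lexicon)
    cm <- confusion_counts(labels[test_idx], pred$.pred_class)
    per_fold[[f]] <- dplyr::mutate(compute_metrics(cm), fold = f,
                                   n_test = length(test_idx), .before = 1)
    if (diagnostics) {
      diag_rows[[f]] <- tibble(fold = f, row = test_idx,
                               label = labels[test_idx],
                               predicted = pred$.pred_class,
                               theta = pred$theta)
    }
    if (!quiet) {
      message(sprintf("fold %d/%d  acc %.3f  f1 %.3f", f, folds,
                      per_fold[[f]]$accuracy, per_fold[[f]]$f1))
    }
  }
  fold_metrics <- dplyr::bind_rows(per_fold)
  metric_cols <- c("accuracy", "precision", "recall", "f1")
  summary <- dplyr::bind_rows(
    dplyr::summarise(fold_metrics, dplyr::across(dplyr::all_of(metric_cols), mean),
                     stat = "mean"),
    dplyr::summarise(fold_metrics, dplyr::across(dplyr::all_of(metric_cols), stats::sd),
                     stat = "sd")
  )
  structure(
    list(fold_metrics = fold_metrics, summary = summary,
         variant = config$variant, folds = folds, seed = config$seed,
         diagnostics = if (diagnostics) dplyr::bind_rows(diag_rows)),
    class = "ean_cv"
  )
}

#' @export
print.ean_cv <- function(x, ...) {
  m <- x$summary[x$summary$stat == "mean", ]
  s <- x$summary[x$summary$stat == "sd", ]
  cat("<ean_cv>", x$variant, "-", x$folds, "folds\n")
  for (col in c("accuracy", "precision", "recall", "f1")) {
    cat(sprintf("  %-9s %.2f%% (sd %.2f)\n", col, 100 * m[[col]], 100 * s[[col]]))
  }
  invisible(x)
}

#' Write cross-validation metrics as JSON
#'
#' Emits per-fold metrics plus their mean and standard deviation, with full
#' numeric precision so identical runs produce identical files.
#'
#' @param cv An `ean_cv`.
#' @param path Output path (conventionally `metrics.json`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(cv, path) {
  payload <- list(
    variant = cv$variant,
    folds = cv$folds,
    seed = cv$seed,
    per_fold = cv$fold_metrics,
    mean = as.list(cv$summary[cv$summary$stat == "mean",
                              c("accuracy", "precision", "recall", "f1")]),
    sd = as.list(cv$summary[cv$summary$stat == "sd",
                            c("accuracy", "precision", "recall", "f1")])
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Run an ablation suite
#'
#' Cross-validates each requested variant at each seed and tabulates the
#' mean and standard deviation of accuracy, precision, recall and F1 — the
#' shape of the published ablation comparisons (full model vs single-branch
#' models vs alternative fusion strategies).
#'
#' @param corpus Tibble with `text` and `label`.
#' @param lexicon A `polarity_lexicon`.
#' @param config Base [ean_config()]; its `variant` and `seed` are overridden.
#' @param variants Character vector of variant names.
#' @param seeds Integer vector of seeds.
#' @param folds Folds per cross-validation run.
#' @param quiet Suppress progress messages.
#' @return An `ean_ablation`: list with `runs` (one row per variant x seed x
#'   fold) and `table` (one row per variant, mean and sd columns).
#' @export
run_ablation_suite <- function(corpus, lexicon = NULL, config = ean_config(),
                               variants = c("EAN", "SUN", "EUN"),
                               seeds = 0L, folds = 10L, quiet = TRUE) {
  bad <- setdiff(variants, ean_variants())
  if (length(bad) > 0L) {
    abort(paste0("unknown variant(s): ", paste(bad, collapse = ", "),
                 "; valid names: ", paste(ean_variants(), collapse = ", ")))
  }
  grid <- tidyr::expand_grid(variant = variants, seed = as.integer(seeds))
  runs <- purrr::pmap(grid, function(variant, seed) {
    cfg <- config
    cfg$variant <- variant
    cfg$seed <- seed
    cv <- cross_validate(corpus, lexicon, cfg, folds = folds, quiet = TRUE)
    if (!quiet) {
      m <- cv$summary[cv$summary$stat == "mean", ]
      message(sprintf("%-18s seed %d  acc %.3f  f1 %.3f",
                      variant, seed, m$accuracy, m$f1))
    }
    dplyr::mutate(cv$fold_metrics, variant = variant, seed = seed, .before = 1)
  })
  runs <- dplyr::bind_rows(runs)
  metric_cols <- c("accuracy", "precision", "recall", "f1")
  table <- runs |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metric_cols),
                    list(mean = mean, sd = stats::sd)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$variant, variants))
  structure(list(runs = runs, table = table, seeds = as.integer(seeds),
                 folds = folds),
            class = "ean_ablation")
}

#' @export
print.ean_ablation <- function(x, ...) {
  cat("<ean_ablation>", length(unique(x$runs$variant)), "variants x",
      length(x$seeds), "seed(s) x", x$folds, "folds\n")
  print(as.data.frame(x$table), digits = 3)
  invisible(x)
}

#' Export an ablation table
#'
#' @param ablation An `ean_ablation`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The ablation object, invisibly.
#' @export
export_ablation <- function(ablation, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(ablation$table, csv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(table = ablation$table, runs = ablation$runs),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(ablation)
}
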