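#' Tidy a trained model's history
#'
#' @param x An `ean_fit`.
#' @param ... Unused.
#' @return The per-epoch training log as a tibble: `epoch`, `loss`,
#'   `val_loss`, `val_accuracy`.
#' @method tidy ean_fit
#' @export
tidy.ean_fit <- function(x, ...) x$history

#' One-row summary of a trained model
#'
#' @param x An `ean_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variant, epochs run, best epoch, final training
#'   loss, held-out loss/accuracy at the final epoch, and parameter count.
#' @method glance ean_fit
#' @export
glance.ean_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(
    variant = x$model$variant,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    loss = last$loss,
    val_loss = last$val_loss,
    val_accuracy = last$val_accuracy,
    n_parameters = sum(vapply(x$model$params, length, integer(1)))
  )
}

#' Tidy cross-validation results
#'
#' @param x An `ean_cv`.
#' @param ... Unused.
#' @return Per-fold metrics as a tibble.
#' @method tidy ean_cv
#' @export
tidy.ean_cv <- function(x, ...) x$fold_metrics

#' One-row summary of a cross-validation run
#'
#' @param x An `ean_cv`.
#' @param ... Unused.
#' @return A one-row tibble with fold-mean accuracy, precision, recall, F1
#'   and their standard deviations.
#' @method glance ean_cv
#' @export
glance.ean_cv <- function(x, ...) {
  m <- x$summary[x$summary$stat == "mean", c("accuracy", "precision", "recall", "f1")]
  s <- x$summary[x$summary$stat == "sd", c("accuracy", "precision", "recall", "f1")]
  names(s) <- paste0(names(s), "_sd")
  dplyr::bind_cols(tibble(variant = x$variant, folds = x$folds), m, s)
}

#' Tidy an ablation suite
#'
#' @param x An `ean_ablation`.
#' @param ... Unused.
#' @return One row per variant x seed x fold.
#' @method tidy ean_ablation
#' @export
tidy.ean_ablation <- function(x, ...) x$runs

#' Plot a training history
#'
#' @param object An `ean_fit`.
#' @param ... Unused.
#' @return A ggplot of training and held-out loss per epoch.
#' @method autoplot ean_fit
#' @export
autoplot.ean_fit <- function(object, ...) {
  df <- object$history |>
    tidyr::pivot_longer(dplyr::any_of(c("loss", "val_loss")),
                        names_to = "series", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(
      values = c(loss = "#1b7837", val_loss = "#762a83"),
      labels = c(loss = "training", val_loss = "held-out")
    ) +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL,
                  title = paste(object$model$variant, "training history")) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `ean_cv`.
#' @param ... Unused.
#' @return A ggplot with one point per fold and a crossbar at the mean.
#' @method autoplot ean_cv
#' @export
autoplot.ean_cv <- function(object, ...) {
  df <- object$fold_metrics |>
    tidyr::pivot_longer(dplyr::all_of(c("accuracy", "precision", "recall", "f1")),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "#b2182b") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste(object$variant, "-", object$folds, "fold CV")) +
    ggplot2::theme_minimal()
}

#' Plot an ablation comparison
#'
#' @param object An `ean_ablation`.
#' @param metric Which metric to show.
#' @param ... Unused.
#' @return A ggplot bar chart (mean over runs, error bar = one standard
#'   deviation), mirroring the usual ablation figure layout.
#' @method autoplot ean_ablation
#' @export
autoplot.ean_ablation <- function(object, metric = "accuracy", ...) {
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(.data$variant, .data[[mcol]])) +
    ggplot2::geom_col(fill = "#2166ac", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                        ymax = .data[[mcol]] + .data[[scol]]),
                           width = 0.15) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Plot per-class fusion-gate shares
#'
#' @param object A `theta_report`.
#' @param ... Unused.
#' @return A stacked bar chart of the mean positive share (theta) and
#'   negative share (1 - theta) per class.
#' @method autoplot theta_report
#' @export
autoplot.theta_report <- function(object, ...) {
  df <- object$per_class |>
    tidyr::pivot_longer(dplyr::all_of(c("mean_theta", "mean_one_minus_theta")),
                        names_to = "share", values_to = "value") |>
    dplyr::mutate(
      class = ifelse(.data$label == 1L, "depression-indicative", "standard"),
      share = ifelse(.data$share == "mean_theta",
                     "positive (theta)", "negative (1 - theta)")
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$value, fill = .data$share)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::scale_fill_manual(values = c("positive (theta)" = "#4393c3",
                                          "negative (1 - theta)" = "#d6604d")) +
    ggplot2::labs(x = NULL, y = "mean gate share", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Save and load a trained model
#'
#' Writes the parameter archive (`params.rds`) and a JSON sidecar recording
#' the architecture and configuration, so a checkpoint is self-describing.
#'
#' @param fit An `ean_fit`.
#' @param dir Checkpoint directory (created if missing).
#' @return `dir` (for `save_ean`) or the restored `ean_fit` (for
#'   `load_ean`), invisibly for the writer.
#' @export
save_ean <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(fit$model$params, file.path(dir, "params.rds"))
  meta <- fit$model[c("variant", "units", "dim", "ctx_dim", "branches",
                      "bidirectional", "attention", "fusion_mode",
                      "feature_dim", "max_len", "max_len_emo")]
  meta$config <- unclass(fit$config)
  meta$vocab_words <- fit$model$vocab$words
  meta$best_epoch <- fit$best_epoch
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(fit$history, file.path(dir, "history.rds"))
  invisible(dir)
}

#' @rdname save_ean
#' @export
load_ean <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "config.json"))
  model <- meta[c("variant", "units", "dim", "ctx_dim", "branches",
                  "bidirectional", "attention", "fusion_mode",
                  "feature_dim", "max_len", "max_len_emo")]
  model$vocab <- new_vocab(meta$vocab_words)
  model$params <- readRDS(file.path(dir, "params.rds"))
  cfg <- meta$config
  model$config <- do.call(ean_config, cfg[names(cfg) %in% names(formals(ean_config))])
  structure(
    list(model = structure(model, class = "ean_model"),
         history = readRDS(file.path(dir, "history.rds")),
         best_epoch = meta$best_epoch,
         config = model$config),
    class = "ean_fit"
  )
}
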