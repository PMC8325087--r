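test_that("metrics match the hand formulas on the worked confusion matrix", {
  m <- compute_metrics(c(tp = 3, fp = 1, fn = 1, tn = 5))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)

  perfect <- compute_metrics(c(tp = 7, fp = 0, fn = 0, tn = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
})

test_that("zero denominators yield 0 with a warning", {
  expect_warning(m <- compute_metrics(c(tp = 0, fp = 0, fn = 2, tn = 8)),
                 "precision")
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
  expect_equal(m$accuracy, 0.8)
})

test_that("metrics agree with an independent oracle on random counts", {
  withr::with_seed(31, {
    for (i in 1:1000) {
      cm <- as.list(setNames(rpois(4, sample(c(0, 1, 5, 40), 4, TRUE)),
                             c("tp", "fp", "fn", "tn")))
      if (Reduce(`+`, cm) == 0) cm$tn <- 1
      m <- suppressWarnings(compute_metrics(cm))
      ref <- oracle_metrics(cm$tp, cm$fp, cm$fn, cm$tn)
      expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
                   ref, tolerance = 1e-12, ignore_attr = TRUE)
    }
  })
})

test_that("stratified folds partition the corpus with balanced classes", {
  labels <- rep(c(1L, 0L), c(50L, 50L))
  fold <- stratified_folds(labels, 10, seed = 0)
  expect_equal(sort(unique(fold)), 1:10)
  # disjoint and exhaustive by construction of an assignment vector; check sizes
  expect_equal(unname(table(fold)), rep(10L, 10), ignore_attr = TRUE)
  for (f in 1:10) {
    expect_equal(sum(labels[fold == f] == 1L), 5L)
  }

  # imbalanced corpus: per-fold class ratio within one post of the corpus ratio
  labels2 <- rep(c(1L, 0L), c(70L, 30L))
  fold2 <- stratified_folds(labels2, 10, seed = 3)
  for (f in 1:10) {
    expect_equal(sum(labels2[fold2 == f] == 1L), 7L)
    expect_equal(sum(labels2[fold2 == f] == 0L), 3L)
  }

  expect_error(stratified_folds(rep(c(1L, 0L), c(95L, 5L)), 10),
               "fewer folds")
})

test_that("cross-validation tests every post exactly once and is deterministic", {
  corp <- separable_corpus(n_per_class = 10)
  lex <- tiny_lexicon()
  cfg <- tiny_config(epochs = 1L)
  cv1 <- suppressWarnings(cross_validate(corp, lex, cfg, folds = 2,
                                         diagnostics = TRUE))
  expect_equal(sum(cv1$fold_metrics$n_test), nrow(corp))
  expect_equal(sort(cv1$diagnostics$row), seq_len(nrow(corp)))
  expect_equal(anyDuplicated(cv1$diagnostics$row), 0L)

  cv2 <- suppressWarnings(cross_validate(corp, lex, cfg, folds = 2,
                                         diagnostics = TRUE))
  expect_identical(cv1$fold_metrics, cv2$fold_metrics)

  g <- glance(cv1)
  expect_equal(g$accuracy, mean(cv1$fold_metrics$accuracy))
  expect_equal(nrow(tidy(cv1)), 2L)
})

test_that("metrics files from identical runs are byte-identical", {
  corp <- separable_corpus(n_per_class = 10)
  lex <- tiny_lexicon()
  cfg <- tiny_config(epochs = 1L)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_metrics(suppressWarnings(cross_validate(corp, lex, cfg, folds = 2)), f1)
  write_metrics(suppressWarnings(cross_validate(corp, lex, cfg, folds = 2)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the ablation suite tabulates variants deterministically", {
  corp <- separable_corpus(n_per_class = 10)
  lex <- tiny_lexicon()
  cfg <- tiny_config(epochs = 1L)
  ab <- suppressWarnings(
    run_ablation_suite(corp, lex, cfg, variants = c("EAN", "SUN"),
                       seeds = 0L, folds = 2)
  )
  expect_equal(nrow(ab$table), 2L)
  expect_equal(ab$table$variant, c("EAN", "SUN"))
  expect_true(all(c("accuracy_mean", "accuracy_sd", "f1_mean") %in%
                    names(ab$table)))
  expect_equal(nrow(ab$runs), 2L * 2L)

  ab2 <- suppressWarnings(
    run_ablation_suite(corp, lex, cfg, variants = c("EAN", "SUN"),
                       seeds = 0L, folds = 2)
  )
  expect_identical(ab$table, ab2$table)

  expect_error(run_ablation_suite(corp, lex, cfg, variants = "NOPE"),
               "valid names")

  csv <- withr::local_tempfile(fileext = ".csv")
  export_ablation(ab, csv_path = csv)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 2L)
})
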