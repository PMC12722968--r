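test_that("confusion counts match a brute-force tally and conserve n", {
  truth <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  cm <- confusion_matrix(truth, truth)
  expect_equal(unlist(cm), c(tp = 6, fp = 0, fn = 0, tn = 4))
  # inverted predictions swap tp<->fn and tn<->fp
  inv <- confusion_matrix(truth, 1 - truth)
  expect_equal(unlist(inv), c(tp = 0, fp = 4, fn = 6, tn = 0))
  # random case against an explicit row-by-row tally
  set.seed(5)
  t2 <- rbinom(50, 1, 0.5); p2 <- rbinom(50, 1, 0.5)
  cm2 <- confusion_matrix(t2, p2)
  tally <- table(factor(p2, 0:1), factor(t2, 0:1))
  expect_equal(cm2$tp, tally["1", "1"][[1]])
  expect_equal(cm2$fp, tally["1", "0"][[1]])
  expect_equal(cm2$fn, tally["0", "1"][[1]])
  expect_equal(cm2$tn, tally["0", "0"][[1]])
  expect_equal(cm2$tp + cm2$fp + cm2$fn + cm2$tn, 50)
  expect_error(confusion_matrix(c(0, 1), c(1)), "length")
  expect_error(confusion_matrix(c(0, 2), c(1, 1)), "binary")
})

test_that("percentage metrics follow the printed formulas", {
  m <- classification_metrics(tibble::tibble(tp = 45, fp = 5, fn = 5, tn = 45))
  expect_equal(m$precision, 90)
  expect_equal(m$recall, 90)
  expect_equal(m$f1, 90)
  expect_equal(m$accuracy, 90)
  expect_equal(m$false_rate, 10)
  perfect <- classification_metrics(tibble::tibble(tp = 7, fp = 0, fn = 0, tn = 3))
  expect_true(all(unlist(perfect[c("precision", "recall", "f1", "accuracy")]) == 100))
  expect_equal(perfect$false_rate, 0)
})

test_that("zero denominators surface as undefined, never as silent zero", {
  m <- classification_metrics(tibble::tibble(tp = 0, fp = 0, fn = 4, tn = 6))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  expect_equal(m$recall, 0)
  expect_equal(m$accuracy, 60)
})

test_that("metric identities hold on enumerated confusion matrices", {
  grid <- expand.grid(tp = 0:3, fp = 0:3, fn = 0:3, tn = 0:3)
  grid <- grid[rowSums(grid) > 0, ]
  for (i in seq_len(nrow(grid))) {
    m <- classification_metrics(tibble::as_tibble(grid[i, ]))
    expect_equal(m$accuracy + m$false_rate, 100, tolerance = 1e-12)
    if (!is.na(m$f1)) {
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
      # percentage-scale F1 equals fraction-scale F1 times 100
      pr <- m$precision / 100; rc <- m$recall / 100
      expect_equal(m$f1, 100 * 2 * pr * rc / (pr + rc), tolerance = 1e-12)
    }
  }
})

test_that("model comparison shares splits, beats the majority baseline, repeats", {
  tab <- generate_pd_dataset(n_rows = 250, n_informative = 3, n_noise = 4,
                             effect_size = 3, class_balance = 0.6, seed = 12)
  pre <- preprocess(tab)
  cfg <- list(mfnn = list(
    fit = function(train, val, label_col, seed) {
      mfnn(train, validation = val, n_rules = 4, epochs = 80, seed = seed,
           label_col = label_col)
    },
    predict = function(fit, newdata) predict(fit, newdata, type = "class")
  ), majority = "majority")
  res <- compare_models(pre, models = cfg, seeds = 1:2)
  expect_false(any(res$failed))
  acc <- tidyr::pivot_wider(res[c("model", "seed", "accuracy")],
                            names_from = "model", values_from = "accuracy")
  expect_true(all(acc$mfnn > acc$majority))
  # majority-class accuracy tracks the class prior (60/40)
  expect_true(all(abs(res$accuracy[res$model == "majority"] - 60) < 10))
  res2 <- compare_models(pre, models = cfg, seeds = 1:2)
  expect_identical(as.data.frame(res2), as.data.frame(res))
})

test_that("a failing model is recorded without aborting the comparison", {
  pre <- preprocess(make_worked_toy())
  bad <- list(bad = list(fit = function(...) stop("boom"),
                         predict = function(...) NULL),
              majority = "majority")
  res <- suppressWarnings(compare_models(pre, models = bad, seeds = 1))
  expect_true(res$failed[res$model == "bad"])
  expect_false(res$failed[res$model == "majority"])
})
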