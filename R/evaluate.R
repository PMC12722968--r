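#' Confusion matrix for binary predictions
#'
#' @param truth True labels, 0/1.
#' @param estimate Predicted labels, 0/1, same length.
#' @return A one-row tibble with counts `tp`, `fp`, `fn`, `tn`
#'   (`tp` = predicted 1 and truly 1); the four counts sum to the number
#'   of rows evaluated.
#' @examples
#' confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_matrix <- function(truth, estimate) {
  if (length(truth) != length(estimate)) abort("`truth` and `estimate` differ in length.")
  if (!all(truth %in% c(0, 1)) || !all(estimate %in% c(0, 1))) {
    abort("`truth` and `estimate` must be binary 0/1 vectors.")
  }
  tibble(tp = sum(estimate == 1 & truth == 1),
         fp = sum(estimate == 1 & truth == 0),
         fn = sum(estimate == 0 & truth == 1),
         tn = sum(estimate == 0 & truth == 0))
}

#' Classification metrics from a confusion matrix, on the percentage scale
#'
#' Precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, their harmonic mean F1,
#' accuracy `(tp+tn)/n` and the false rate `(fp+fn)/n`, all multiplied by
#' 100. A metric with a zero denominator is reported as `NA` — an explicit
#' "undefined" marker, never silently 0 — so degenerate classifiers are
#' visible in comparisons.
#'
#' @param cm A one-row tibble from [confusion_matrix()] (columns `tp`,
#'   `fp`, `fn`, `tn`).
#' @return A one-row tibble: `precision`, `recall`, `f1`, `accuracy`,
#'   `false_rate`, `n`. `accuracy + false_rate = 100`.
#' @examples
#' classification_metrics(tibble::tibble(tp = 45, fp = 5, fn = 5, tn = 45))
#' @export
classification_metrics <- function(cm) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(cm)))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  precision <- safe(cm$tp, cm$tp + cm$fp)
  recall <- safe(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble(precision = precision, recall = recall, f1 = f1,
         accuracy = safe(cm$tp + cm$tn, n),
         false_rate = safe(cm$fp + cm$fn, n),
         n = n)
}

#' Evaluate predictions against truth in one call
#'
#' @param truth,estimate Binary 0/1 vectors.
#' @return The [classification_metrics()] tibble with the confusion counts
#'   bound in front.
#' @export
evaluate_predictions <- function(truth, estimate) {
  cm <- confusion_matrix(truth, estimate)
  dplyr::bind_cols(cm, classification_metrics(cm))
}

# built-in model specifications for compare_models()
builtin_model_spec <- function(name) {
  switch(name,
    mfnn = list(
      fit = function(train, val, label_col, seed) {
        mfnn(train, validation = val, seed = seed, label_col = label_col)
      },
      predict = function(fit, newdata) predict(fit, newdata, type = "class")
    ),
    majority = list(
      fit = function(train, val, label_col, seed) {
        as.integer(mean(train[[label_col]]) >= 0.5)
      },
      predict = function(fit, newdata) rep(fit, nrow(newdata))
    ),
    logistic = list(
      fit = function(train, val, label_col, seed) {
        df <- as.data.frame(train, check.names = TRUE)
        names(df)[names(df) == label_col] <- ".y"
        suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      },
      predict = function(fit, newdata) {
        df <- as.data.frame(newdata, check.names = TRUE)
        as.integer(predict(fit, df, type = "response") >= 0.5)
      }
    ),
    abort(sprintf("Unknown built-in model '%s'.", name))
  )
}

#' Compare classifiers on shared splits
#'
#' Fits each model on identical train/validation partitions across a set
#' of seeds and evaluates all of them on the shared held-out test
#' partition, so differences reflect the models, not the splits. Built-in
#' specifications: `"mfnn"` (the fuzzy network with defaults),
#' `"majority"` (majority-class baseline) and `"logistic"`
#' (logistic-regression baseline); a custom model is a
#' `list(fit = function(train, val, label_col, seed), predict =
#' function(fit, newdata))`. A model that fails to train is recorded as a
#' failed row and the run continues.
#'
#' @param data Preprocessed feature table.
#' @param models Character vector of built-in names and/or a named list of
#'   custom specs. Default `c("mfnn", "majority")`.
#' @param seeds Integer vector of split/training seeds. Default `1:3`.
#' @param train_frac,val_frac,test_frac Split fractions. Defaults
#'   0.6/0.2/0.2.
#' @param label_col Label column name.
#' @return A tibble with one row per model x seed: the metric columns of
#'   [classification_metrics()] plus `model`, `seed`, `failed`.
#' @export
compare_models <- function(data, models = c("mfnn", "majority"), seeds = 1:3,
                           train_frac = 0.6, val_frac = 0.2, test_frac = 0.2,
                           label_col = "status") {
  if (is.character(models)) models <- setNames(as.list(models), models)
  if (length(models) < 1) abort("Need at least one model spec.")
  specs <- purrr::imap(models, function(m, nm) {
    if (is.character(m)) builtin_model_spec(m) else m
  })
  purrr::map_dfr(seeds, function(sd) {
    sp <- split_dataset(data, train_frac, val_frac, test_frac,
                        seed = sd, label_col = label_col)
    train <- partition(sp, "train")
    val <- partition(sp, "validation")
    test <- partition(sp, "test")
    purrr::imap_dfr(specs, function(spec, nm) {
      res <- tryCatch({
        fit <- spec$fit(train, val, label_col, sd)
        pred <- spec$predict(fit, test)
        ev <- evaluate_predictions(test[[label_col]], pred)
        dplyr::bind_cols(tibble(model = nm, seed = sd, failed = FALSE), ev)
      }, error = function(e) {
        tibble(model = nm, seed = sd, failed = TRUE)
      })
      res
    })
  })
}
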