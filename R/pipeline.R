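#' Default pipeline configuration
#'
#' Collects every tunable setting of the four-stage pipeline in one list,
#' so paper-silent defaults are explicit and auditable. Any entry can be
#' overridden by name, e.g. `pd_config(ldefs = list(threshold = 0.9))`
#' (partial lists are merged into the defaults).
#'
#' @param ... Named overrides for the sections `split`, `preprocess`,
#'   `dasr`, `ldefs`, `mfnn`, `risk`, or the scalars `label_col`.
#' @return A nested configuration list.
#' @export
pd_config <- function(...) {
  defaults <- list(
    label_col = "status",
    split = list(train_frac = 0.6, val_frac = 0.2, test_frac = 0.2,
                 stratified = TRUE),
    preprocess = list(policy = "impute_mean", z_cutoff = 4,
                      max_missing = 0.2, fit_on = "train"),
    dasr = list(e_rate = 0.05),
    ldefs = list(threshold = 0.85, k_min = 4, n_bins = 10),
    mfnn = list(n_rules = 4, epochs = 300, learning_rate = 0.6,
                momentum = 0.9, patience = 30, t_norm = "product",
                width_floor = 0.05),
    risk = list(thresholds = c(0.33, 0.66))
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) abort(sprintf("Unknown config section(s): %s", paste(bad, collapse = ", ")))
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Run the full prediction pipeline
#'
#' Executes the four stages in order on one table: split, preprocessing
#' (z-score + min-max with cleaning), DASR feature weighting, LDEFS
#' feature selection, fuzzy-network training, and held-out evaluation with
#' risk stratification. Preprocessing statistics are fitted on the
#' training partition and frozen for validation/test
#' (`preprocess$fit_on = "all"` instead normalizes the collective table
#' before splitting). Fully deterministic under `seed`; every stage output
#' is hashed into a run manifest.
#'
#' @param data Feature table with a binary label column (e.g. from
#'   [read_feature_table()] or [generate_pd_dataset()]).
#' @param seed Integer seed driving the split and the network
#'   initialization.
#' @param config Configuration list from [pd_config()].
#' @return An object of class `"pd_pipeline"`: a list with `report`
#'   (held-out confusion counts and percentage metrics), `risk` (per
#'   risk-class counts on the test partition), `weights` (DASR table),
#'   `selection` (LDEFS table; the ordered selected features in attribute
#'   `"finest"`), `model` (the fitted `"mfnn"`), `split_sizes`, `manifest`
#'   (stage, output hash, elapsed seconds), `seed` and `config`.
#' @examples
#' tab <- generate_pd_dataset(n_rows = 200, n_informative = 3, n_noise = 5,
#'                            effect_size = 2.5, seed = 3)
#' res <- run_pipeline(tab, seed = 3,
#'                     config = pd_config(mfnn = list(epochs = 60)))
#' res$report
#' @export
run_pipeline <- function(data, seed = 1, config = pd_config()) {
  check_feature_table(data, config$label_col)
  label_col <- config$label_col
  manifest <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = name, hash = rlang::hash(out),
      elapsed = proc.time()[["elapsed"]] - t0)
    out
  }

  if (identical(config$preprocess$fit_on, "all")) {
    pre_all <- preprocess(data, policy = config$preprocess$policy,
                          z_cutoff = config$preprocess$z_cutoff,
                          max_missing = config$preprocess$max_missing,
                          label_col = label_col)
    sp <- split_dataset(pre_all, config$split$train_frac, config$split$val_frac,
                        config$split$test_frac, seed = seed,
                        stratified = config$split$stratified, label_col = label_col)
    pre_train <- partition(sp, "train")
    pre_val <- partition(sp, "validation")
    pre_test <- partition(sp, "test")
    stage("preprocess", pre_all)
  } else {
    sp <- split_dataset(data, config$split$train_frac, config$split$val_frac,
                        config$split$test_frac, seed = seed,
                        stratified = config$split$stratified, label_col = label_col)
    pre_train <- stage("preprocess", preprocess(
      partition(sp, "train"), policy = config$preprocess$policy,
      z_cutoff = config$preprocess$z_cutoff,
      max_missing = config$preprocess$max_missing, label_col = label_col))
    stats <- attr(pre_train, "stats")
    pre_val <- preprocess(partition(sp, "validation"), stats = stats,
                          label_col = label_col)
    pre_test <- preprocess(partition(sp, "test"), stats = stats,
                           label_col = label_col)
  }

  weights <- stage("dasr", dasr_weights(pre_train, e_rate = config$dasr$e_rate,
                                        label_col = label_col))
  selection <- stage("select", ldefs(pre_train,
                                     threshold = config$ldefs$threshold,
                                     k_min = config$ldefs$k_min,
                                     n_bins = config$ldefs$n_bins,
                                     label_col = label_col))
  f_b <- attr(selection, "finest")
  model <- stage("train", mfnn(pre_train, features = f_b,
                               n_rules = config$mfnn$n_rules,
                               epochs = config$mfnn$epochs,
                               learning_rate = config$mfnn$learning_rate,
                               momentum = config$mfnn$momentum,
                               patience = config$mfnn$patience,
                               validation = pre_val,
                               t_norm = config$mfnn$t_norm,
                               width_floor = config$mfnn$width_floor,
                               seed = seed, label_col = label_col))
  report <- stage("evaluate", {
    pred <- predict(model, pre_test, type = "class")
    evaluate_predictions(pre_test[[label_col]], pred)
  })
  risk <- predict(model, pre_test, type = "risk",
                  thresholds = config$risk$thresholds) %>%
    dplyr::count(.data$risk_class, name = "n_rows", .drop = FALSE)

  structure(list(
    report = report,
    risk = risk,
    weights = weights,
    selection = selection,
    model = model,
    split_sizes = c(train = nrow(pre_train), validation = nrow(pre_val),
                    test = nrow(pre_test)),
    manifest = bind_rows(manifest),
    seed = seed,
    config = config
  ), class = "pd_pipeline")
}

#' @export
print.pd_pipeline <- function(x, ...) {
  cat("Parkinson's voice-feature pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("Selected features:", paste(attr(x$selection, "finest"), collapse = ", "), "\n")
  cat(sprintf("Held-out (n = %d): accuracy %.1f%%, precision %s, recall %s, F1 %s, false rate %.1f%%\n",
              x$report$n, x$report$accuracy,
              fmt_pct(x$report$precision), fmt_pct(x$report$recall),
              fmt_pct(x$report$f1), x$report$false_rate))
  invisible(x)
}

fmt_pct <- function(x) if (is.na(x)) "undefined" else sprintf("%.1f%%", x)

#' Serialize a pipeline report to JSON
#'
#' Writes the held-out report, risk counts, selected features, split sizes
#' and manifest as pretty JSON; [read_pipeline_report()] reads it back.
#'
#' @param result A `"pd_pipeline"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(result, path) {
  payload <- list(
    seed = result$seed,
    split_sizes = as.list(result$split_sizes),
    selected_features = attr(result$selection, "finest"),
    report = as.list(result$report),
    risk = setNames(as.list(result$risk$n_rows),
                    as.character(result$risk$risk_class)),
    manifest = result$manifest
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a serialized pipeline report
#'
#' @param path Path written by [write_pipeline_report()].
#' @return The report as a list (tibbles restored for `report` and
#'   `manifest`).
#' @export
read_pipeline_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$report <- as_tibble(x$report)
  x$manifest <- as_tibble(x$manifest)
  x
}
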