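#' Tidy a fitted fuzzy network
#'
#' Returns one row per trainable parameter: fuzzy-set centers and widths,
#' consequent coefficients and biases, and the class-head weights.
#'
#' @param x An `"mfnn"` object.
#' @param ... Unused.
#' @return A tibble with `term` (parameter group), `rule`, `feature`
#'   (`NA` for rule- or class-level terms), `class` and `estimate`.
#' @export
tidy.mfnn <- function(x, ...) {
  R <- nrow(x$centers); d <- length(x$features)
  grid <- tidyr::expand_grid(rule = seq_len(R), feature = x$features)
  per_rf <- bind_rows(
    mutate(grid, term = "center", estimate = as.vector(t(x$centers))),
    mutate(grid, term = "width", estimate = as.vector(t(x$widths))),
    mutate(grid, term = "consequent", estimate = as.vector(t(x$p)))
  )
  rule_level <- tibble(term = "bias", rule = seq_len(R),
                       feature = NA_character_, estimate = x$q)
  head_level <- tidyr::expand_grid(class = 0:1, rule = seq_len(R)) %>%
    mutate(term = "class_weight", feature = NA_character_,
           estimate = as.vector(t(x$V)))
  bias_level <- tibble(term = "class_bias", class = 0:1,
                       feature = NA_character_, estimate = x$v0)
  bind_rows(per_rf, rule_level, head_level, bias_level) %>%
    select(dplyr::any_of(c("term", "rule", "class", "feature", "estimate")))
}

#' One-row summary of a fitted fuzzy network
#'
#' @param x An `"mfnn"` object.
#' @param ... Unused.
#' @return A tibble: `n_rules`, `n_features`, `epochs_run`, final
#'   `train_loss` and `val_loss`.
#' @export
glance.mfnn <- function(x, ...) {
  last <- if (nrow(x$history)) x$history[nrow(x$history), ] else
    tibble(train_loss = NA_real_, val_loss = NA_real_)
  tibble(n_rules = nrow(x$centers), n_features = length(x$features),
         epochs_run = x$epochs_run %||% 0L,
         train_loss = last$train_loss, val_loss = last$val_loss)
}

#' Augment a feature table with fuzzy-network predictions
#'
#' @param x An `"mfnn"` object.
#' @param data Feature table containing the model's inputs.
#' @param thresholds Risk thresholds, see [assign_risk()].
#' @param ... Unused.
#' @return `data` with added `.p_pd`, `.pred_label` and `.risk_class`
#'   columns.
#' @export
augment.mfnn <- function(x, data, thresholds = c(0.33, 0.66), ...) {
  r <- predict(x, data, type = "risk", thresholds = thresholds)
  mutate(as_tibble(data), .p_pd = r$p_pd, .pred_label = r$label,
         .risk_class = r$risk_class)
}

#' Tidy a pipeline run
#'
#' @param x A `"pd_pipeline"` object.
#' @param ... Unused.
#' @return The per-feature stage table: DASR weights joined with the LDEFS
#'   gain/score/selection columns.
#' @export
tidy.pd_pipeline <- function(x, ...) {
  left_join(x$weights, x$selection, by = "feature")
}

#' One-row summary of a pipeline run
#'
#' @param x A `"pd_pipeline"` object.
#' @param ... Unused.
#' @return The held-out evaluation report with seed and partition sizes.
#' @export
glance.pd_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    tibble(seed = x$seed,
           n_train = x$split_sizes[["train"]],
           n_validation = x$split_sizes[["validation"]],
           n_test = x$split_sizes[["test"]],
           n_selected = sum(x$selection$selected)),
    x$report
  )
}
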