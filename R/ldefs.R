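#' Shannon entropy of a discrete vector, in bits
#'
#' \eqn{H = -\sum_c p_c \log_2 p_c} with the convention
#' \eqn{0 \log 0 = 0}.
#'
#' @param x Non-empty vector of discrete outcomes (the binary label here).
#' @return Entropy in bits.
#' @examples
#' entropy_bits(c(0, 1, 0, 1)) # 1 bit
#' @export
entropy_bits <- function(x) {
  if (length(x) == 0) abort("`x` must be non-empty.")
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# equal-frequency discretization; features with few distinct values keep
# one bin per value so a 0/1 feature is never collapsed into a single bin
discretize_ef <- function(x, n_bins = 10) {
  ux <- unique(x)
  if (length(ux) <= n_bins) return(match(x, sort(ux)))
  breaks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                            type = 7, names = FALSE))
  if (length(breaks) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = breaks, include.lowest = TRUE))
}

#' Information gain of a feature about the class label, in bits
#'
#' The feature is discretized into equal-frequency bins (features with at
#' most `n_bins` distinct values get one bin per value) and the gain is the
#' reduction in label entropy:
#' \eqn{IG = H(Y) - \sum_b (n_b/N)\, H(Y \mid bin\ b)}. Always in
#' \eqn{[0, H(Y)]}; a constant feature has gain 0.
#'
#' @param x Numeric feature vector.
#' @param y Label vector of the same length.
#' @param n_bins Number of equal-frequency bins. Default 10.
#' @return Information gain in bits.
#' @export
information_gain <- function(x, y, n_bins = 10) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  b <- discretize_ef(x, n_bins)
  h_y <- entropy_bits(y)
  h_cond <- 0
  for (lev in unique(b)) {
    idx <- b == lev
    h_cond <- h_cond + mean(idx) * entropy_bits(y[idx])
  }
  max(h_y - h_cond, 0)
}

#' Information-gain table for every feature
#'
#' @param data Feature table with a label column.
#' @param n_bins Equal-frequency bins for discretization. Default 10.
#' @param label_col Label column name.
#' @return A tibble with `feature`, `gain` (bits) and `h_y` (label entropy,
#'   bits, identical across rows).
#' @export
gain_table <- function(data, n_bins = 10, label_col = "status") {
  check_feature_table(data, label_col)
  feats <- feature_cols(data, label_col)
  y <- data[[label_col]]
  tibble(feature = feats,
         gain = purrr::map_dbl(feats, ~ information_gain(data[[.x]], y, n_bins)),
         h_y = entropy_bits(y))
}

#' Logistic decision scores from information gains
#'
#' Maps each feature's gain to a probability-like score in (0, 1): gains
#' are standardized across features (population mean 0, SD 1) and passed
#' through the logistic sigmoid, so the score is monotone in the gain and
#' a feature whose gain sits 1.73 SD above the mean scores about 0.85.
#' When all gains are equal every score is 0.5.
#'
#' @param gains A tibble with a `gain` column (e.g. from [gain_table()]),
#'   or a bare numeric vector of gains.
#' @return The tibble with an added `score` column (or a numeric vector of
#'   scores if `gains` was a vector).
#' @export
logistic_decision_scores <- function(gains) {
  g <- if (is.data.frame(gains)) gains$gain else gains
  if (length(g) < 2) abort("Need at least 2 features to standardize gains.")
  m <- mean(g)
  s <- sqrt(sum((g - m)^2) / length(g))
  z <- if (s == 0) rep(0, length(g)) else (g - m) / s
  p <- 1 / (1 + exp(-z))
  if (is.data.frame(gains)) dplyr::mutate(gains, score = p) else p
}

#' Threshold selection with a top-k fallback
#'
#' Selects features whose logistic decision score reaches `threshold`
#' (default 0.85). If fewer than `k_min` pass, the top `k_min` by score are
#' selected instead and the fallback is recorded in attribute
#' `"fallback"`. Ties break deterministically by (score descending, name
#' ascending).
#'
#' @param scores Tibble with `feature` and `score` columns.
#' @param threshold Selection threshold in (0, 1). Default 0.85.
#' @param k_min Minimum number of selected features. Default 4.
#' @return `scores` with an added logical `selected` column.
#' @export
select_features <- function(scores, threshold = 0.85, k_min = 4) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  if (k_min < 1) abort("`k_min` must be >= 1.")
  sel <- scores$score >= threshold
  fallback <- FALSE
  if (sum(sel) < k_min) {
    fallback <- TRUE
    ord <- order(-scores$score, scores$feature)
    sel <- seq_len(nrow(scores)) %in% ord[seq_len(min(k_min, nrow(scores)))]
  }
  out <- dplyr::mutate(scores, selected = sel)
  attr(out, "fallback") <- fallback
  out
}

#' Mutual information between a feature and the label, in bits
#'
#' Computed from the joint count table of the equal-frequency-binned
#' feature and the label,
#' \eqn{I = \sum_{b,c} p(b,c) \log_2 \frac{p(b,c)}{p(b)p(c)}}; with the
#' same discretization this equals [information_gain()].
#'
#' @inheritParams information_gain
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, n_bins = 10) {
  b <- discretize_ef(x, n_bins)
  joint <- table(b, y) / length(x)
  pb <- rowSums(joint)
  pc <- colSums(joint)
  mi <- 0
  for (i in seq_along(pb)) for (j in seq_along(pc)) {
    if (joint[i, j] > 0) mi <- mi + joint[i, j] * log2(joint[i, j] / (pb[i] * pc[j]))
  }
  max(mi, 0)
}

#' Order selected features by mutual information (the finest subset)
#'
#' Ranks the selected features by mutual information with the label,
#' descending (ties by name), producing the ordered feature list
#' (`f_b`) that feeds the fuzzy classifier's fuzzification layer.
#'
#' @param data Feature table with a label column.
#' @param selected Character vector of selected feature names.
#' @param n_bins Equal-frequency bins. Default 10.
#' @param label_col Label column name.
#' @return A tibble `feature`, `mi` sorted by `mi` descending.
#' @export
finest_subset <- function(data, selected, n_bins = 10, label_col = "status") {
  if (length(selected) < 1) abort("Need at least one selected feature.")
  missing_f <- setdiff(selected, feature_cols(data, label_col))
  if (length(missing_f)) {
    abort(sprintf("Selected features not in `data`: %s",
                  paste(missing_f, collapse = ", ")))
  }
  y <- data[[label_col]]
  out <- tibble(feature = selected,
                mi = purrr::map_dbl(selected, ~ mutual_information(data[[.x]], y, n_bins)))
  dplyr::arrange(out, desc(.data$mi), .data$feature)
}

#' Logistic decision exhaustive feature selection (LDEFS)
#'
#' The full selection stage: information gain per feature, logistic
#' decision scores, threshold selection with top-`k_min` fallback, and
#' mutual-information ordering of the selected set.
#'
#' @inheritParams gain_table
#' @inheritParams select_features
#' @return A tibble `feature`, `gain`, `h_y`, `score`, `selected`, `mi`
#'   (`mi` is `NA` for unselected features), with attributes
#'   `"finest"` (the MI-descending ordered selected names, `f_b`) and
#'   `"fallback"`.
#' @examples
#' make_worked_toy() |> preprocess() |> ldefs(k_min = 2)
#' @export
ldefs <- function(data, threshold = 0.85, k_min = 4, n_bins = 10,
                  label_col = "status") {
  gt <- gain_table(data, n_bins, label_col)
  sc <- logistic_decision_scores(gt)
  sel <- select_features(sc, threshold, min(k_min, nrow(sc)))
  fs <- finest_subset(data, sel$feature[sel$selected], n_bins, label_col)
  out <- left_join(sel, fs, by = "feature")
  attr(out, "finest") <- fs$feature
  attr(out, "fallback") <- attr(sel, "fallback")
  out
}
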