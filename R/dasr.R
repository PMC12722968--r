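#' Per-feature class-conditional statistics
#'
#' Splits every feature by the binary label and reports count, mean and
#' population variance per class — the ingredients of the disease-affect
#' scaling rate (DASR) weight.
#'
#' @param data (Preprocessed) feature table with a label column.
#' @param label_col Label column name.
#' @return A tibble with one row per feature: `feature`, `n0`, `n1`,
#'   `mean0`, `mean1`, `var0`, `var1`.
#' @export
class_split_stats <- function(data, label_col = "status") {
  check_feature_table(data, label_col)
  lab <- data[[label_col]]
  if (sum(lab == 0L) < 2 || sum(lab == 1L) < 2) {
    abort("Each class needs at least 2 rows for class-split statistics.")
  }
  feats <- feature_cols(data, label_col)
  pop_var <- function(x) sum((x - mean(x))^2) / length(x)
  purrr::map_dfr(feats, function(f) {
    x0 <- data[[f]][lab == 0L]
    x1 <- data[[f]][lab == 1L]
    tibble(feature = f, n0 = length(x0), n1 = length(x1),
           mean0 = mean(x0), mean1 = mean(x1),
           var0 = pop_var(x0), var1 = pop_var(x1))
  })
}

#' Disease-affect scaling rate (DASR) feature weights
#'
#' Scores how strongly each feature separates the healthy and PD classes.
#' Per feature:
#' \describe{
#'   \item{`b_a`}{the pooled-standard-error standardized class-mean
#'     difference \eqn{|m_1 - m_0| / \sqrt{v_0/n_0 + v_1/n_1}}, a t-like
#'     separation statistic (guarded: when both class variances are zero it
#'     is \eqn{|m_1 - m_0| / 10^{-12}} if the means differ, 0 otherwise);}
#'   \item{`w_g`}{the weight, `b_a` normalized to sum to 1 across features;}
#'   \item{`f2`}{the finest-feature score mixing the weight with an assumed
#'     error rate: \eqn{w_g (1 - E) + (1 - w_g) E / T_A} with \eqn{T_A}
#'     the number of features.}
#' }
#' When no feature separates the classes (all `b_a` zero) the weights fall
#' back to uniform `1/T_A` with a warning.
#'
#' @param data (Preprocessed) feature table, or a statistics tibble from
#'   [class_split_stats()].
#' @param e_rate Assumed error rate \eqn{E} in `[0, 1)`. Default 0.05.
#' @param label_col Label column name (ignored when `data` is already a
#'   statistics tibble).
#' @return A tibble with columns `feature`, `b_a`, `w_g`, `f2`, sorted in
#'   the original feature order. `sum(w_g) == 1`.
#' @examples
#' make_worked_toy() |> preprocess() |> dasr_weights()
#' @export
dasr_weights <- function(data, e_rate = 0.05, label_col = "status") {
  if (e_rate < 0 || e_rate >= 1) abort("`e_rate` must be in [0, 1).")
  stats <- if (all(c("mean0", "mean1", "var0", "var1") %in% names(data))) {
    data
  } else {
    class_split_stats(data, label_col)
  }
  t_a <- nrow(stats)
  b_a <- purrr::pmap_dbl(stats, function(mean0, mean1, var0, var1, n0, n1, ...) {
    diff <- abs(mean1 - mean0)
    se <- sqrt(var0 / n0 + var1 / n1)
    if (se == 0) {
      if (diff == 0) 0 else diff / 1e-12
    } else {
      diff / se
    }
  })
  total <- sum(b_a)
  if (total == 0) {
    warn("No feature separates the classes; falling back to uniform weights.")
    w_g <- rep(1 / t_a, t_a)
  } else {
    w_g <- b_a / total
  }
  tibble(feature = stats$feature, b_a = b_a, w_g = w_g,
         f2 = w_g * (1 - e_rate) + (1 - w_g) * e_rate / t_a)
}
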