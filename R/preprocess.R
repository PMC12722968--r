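#' Per-feature summary statistics over present records
#'
#' Computes, for every feature column, the mean and the *population*
#' standard deviation (divide by N, not N-1) over the present (non-missing)
#' records, plus the count of present records. These are the statistics the
#' z-scoring step standardizes with.
#'
#' @param data Feature table with a label column.
#' @param label_col Label column name.
#' @return A tibble with columns `feature`, `mean`, `sd`, `n_present`.
#' @examples
#' column_stats(make_worked_toy())
#' @export
column_stats <- function(data, label_col = "status") {
  feats <- feature_cols(data, label_col)
  stats <- purrr::map_dfr(feats, function(f) {
    x <- data[[f]]
    x <- x[!is.na(x)]
    if (length(x) == 0) abort(sprintf("Feature '%s' has no present values.", f))
    m <- mean(x)
    tibble(feature = f, mean = m,
           sd = sqrt(sum((x - m)^2) / length(x)),
           n_present = length(x))
  })
  stats
}

#' Z-score a feature table
#'
#' Standardizes every feature as `(x - mean) / sd` using population
#' statistics; a constant feature (sd = 0) is centred only, `x - mean`, so
#' the transform is defined by cases on the standard deviation. Missing
#' cells stay missing. When `stats` is supplied (e.g. fitted on the
#' training partition) it is used instead of statistics of `data` itself,
#' which is how validation and test rows are transformed without leakage.
#'
#' @param data Feature table.
#' @param stats Optional tibble from [column_stats()]; must cover exactly
#'   the features of `data`.
#' @param label_col Label column name.
#' @return A tibble of z-scored features with label (and any `.row_id` /
#'   `.split`) carried through.
#' @export
zscore_transform <- function(data, stats = NULL, label_col = "status") {
  feats <- feature_cols(data, label_col)
  if (is.null(stats)) stats <- column_stats(data, label_col)
  if (!setequal(stats$feature, feats)) {
    abort("Feature names in `stats` do not match the features of `data`.")
  }
  out <- data
  for (f in feats) {
    s <- stats[stats$feature == f, ]
    out[[f]] <- if (s$sd != 0) (data[[f]] - s$mean) / s$sd else data[[f]] - s$mean
  }
  out
}

#' Clean a feature table: fill, remove, and trim irrelevant values
#'
#' Missing-value handling followed by z-score outlier removal:
#' \enumerate{
#'   \item Rows with a missing-cell fraction above `max_missing` are dropped
#'     (reason `"missing"`); under `policy = "drop_row"` any missing cell
#'     drops the row.
#'   \item Remaining missing cells are imputed with the feature mean over
#'     present records (`policy = "impute_mean"`).
#'   \item Rows containing any \eqn{|z| >} `z_cutoff` are dropped as
#'     irrelevant values (reason `"irrelevant"`). Trimming repeats until no
#'     such row remains, so the operation is idempotent: the cleaned table
#'     contains no row beyond the cutoff under its own statistics.
#' }
#'
#' @param data Feature table with a label column.
#' @param policy `"impute_mean"` (default) or `"drop_row"`.
#' @param z_cutoff Absolute z-score beyond which a value is irrelevant.
#'   Default 4.
#' @param max_missing Maximum tolerated fraction of missing cells per row
#'   under `impute_mean`. Default 0.2.
#' @param label_col Label column name.
#' @return The cleaned tibble with no missing cells. Dropped rows are
#'   recorded in attribute `"dropped"`, a tibble with `row` (original index)
#'   and `reason`.
#' @export
clean_records <- function(data, policy = c("impute_mean", "drop_row"),
                          z_cutoff = 4, max_missing = 0.2,
                          label_col = "status") {
  policy <- match.arg(policy)
  check_feature_table(data, label_col)
  feats <- feature_cols(data, label_col)
  orig_idx <- seq_len(nrow(data))
  dropped <- tibble(row = integer(), reason = character())

  xm <- as.matrix(data[feats])
  miss_frac <- rowMeans(is.na(xm))
  bound <- if (policy == "drop_row") 0 else max_missing
  drop_missing <- miss_frac > bound
  if (any(drop_missing)) {
    dropped <- bind_rows(dropped, tibble(row = orig_idx[drop_missing],
                                         reason = "missing"))
    data <- data[!drop_missing, , drop = FALSE]
    orig_idx <- orig_idx[!drop_missing]
  }
  if (nrow(data) == 0) abort("All rows dropped during cleaning.")

  # mean-impute the remaining missing cells
  for (f in feats) {
    x <- data[[f]]
    if (anyNA(x)) {
      if (all(is.na(x))) abort(sprintf("Feature '%s' has no present values.", f))
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      data[[f]] <- x
    }
  }

  # iterative z-trim to a fixed point: no surviving row exceeds the cutoff
  # under the surviving rows' own statistics
  repeat {
    stats <- column_stats(data, label_col)
    z <- as.matrix(zscore_transform(data, stats, label_col)[feats])
    bad <- rowSums(abs(z) > z_cutoff) > 0
    if (!any(bad)) break
    dropped <- bind_rows(dropped, tibble(row = orig_idx[bad],
                                         reason = "irrelevant"))
    data <- data[!bad, , drop = FALSE]
    orig_idx <- orig_idx[!bad]
    if (nrow(data) == 0) abort("All rows dropped during cleaning.")
  }
  attr(data, "dropped") <- dplyr::arrange(dropped, .data$row)
  data
}

#' Min-max normalize a z-scored table to [0, 1]
#'
#' Rescales each (z-scored) feature by its min and max so every value lands
#' in `[0, 1]`; a constant feature maps to 0 everywhere (guarded division).
#' With frozen `stats` (columns `z_min`, `z_max`) the training-set range is
#' reused and out-of-range values are clipped into `[0, 1]`.
#'
#' @param data A z-scored feature table with no missing cells.
#' @param stats Optional tibble with columns `feature`, `z_min`, `z_max`.
#' @param label_col Label column name.
#' @return The normalized tibble (the `Pre_D` representation).
#' @export
minmax_normalize <- function(data, stats = NULL, label_col = "status") {
  feats <- feature_cols(data, label_col)
  out <- data
  for (f in feats) {
    x <- data[[f]]
    if (anyNA(x)) abort(sprintf("Feature '%s' still has missing cells; clean first.", f))
    if (is.null(stats)) {
      lo <- min(x); hi <- max(x)
    } else {
      s <- stats[stats$feature == f, ]
      if (nrow(s) != 1) abort(sprintf("No z-range in `stats` for feature '%s'.", f))
      lo <- s$z_min; hi <- s$z_max
    }
    out[[f]] <- if (hi > lo) pmin(pmax((x - lo) / (hi - lo), 0), 1) else rep(0, length(x))
  }
  out
}

#' Preprocess a feature table (clean, z-score, min-max)
#'
#' The full preprocessing stage: [clean_records()], then
#' [zscore_transform()], then [minmax_normalize()]. Called without `stats`
#' it *fits* on `data` and attaches the fitted statistics; called with the
#' `stats` attribute of a previously preprocessed table it *transforms*
#' `data` with the frozen statistics (imputing missing cells with the
#' frozen means, clipping to `[0, 1]`, and dropping no rows), which is how
#' validation and test partitions are prepared without leakage.
#'
#' @inheritParams clean_records
#' @param stats Optional statistics tibble (attribute `"stats"` of a fitted
#'   preprocess result) to transform with instead of fitting.
#' @return A tibble of normalized features in `[0, 1]` plus the label
#'   column, with attributes `"stats"` (feature, mean, sd, n_present,
#'   z_min, z_max) and `"dropped"`.
#' @examples
#' pre <- preprocess(make_worked_toy())
#' range(pre$PPE)
#' @export
preprocess <- function(data, stats = NULL,
                       policy = c("impute_mean", "drop_row"),
                       z_cutoff = 4, max_missing = 0.2,
                       label_col = "status") {
  policy <- match.arg(policy)
  check_feature_table(data, label_col)
  feats <- feature_cols(data, label_col)
  if (is.null(stats)) {
    cleaned <- clean_records(data, policy, z_cutoff, max_missing, label_col)
    cs <- column_stats(cleaned, label_col)
    z <- zscore_transform(cleaned, cs, label_col)
    zr <- purrr::map_dfr(feats, function(f) {
      tibble(feature = f, z_min = min(z[[f]]), z_max = max(z[[f]]))
    })
    out <- minmax_normalize(z, label_col = label_col)
    attr(out, "stats") <- left_join(cs, zr, by = "feature")
    attr(out, "dropped") <- attr(cleaned, "dropped")
  } else {
    if (!setequal(stats$feature, feats)) {
      abort("Feature names in `stats` do not match the features of `data`.")
    }
    for (f in feats) {
      x <- data[[f]]
      x[is.na(x)] <- stats$mean[stats$feature == f]
      data[[f]] <- x
    }
    z <- zscore_transform(data, stats, label_col)
    out <- minmax_normalize(z, stats, label_col)
    attr(out, "stats") <- stats
    attr(out, "dropped") <- tibble(row = integer(), reason = character())
  }
  out
}
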