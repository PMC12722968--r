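#' Read a voice-feature table from CSV
#'
#' Reads a CSV in the UCI/Kaggle Parkinson's voice dialect: a header row,
#' one row per recording, numeric feature columns, and a binary label
#' column (`status` by default, 0 = healthy, 1 = PD). An optional ID column
#' (default `name`) is kept as `.row_id`. The missing-value tokens are the
#' empty string, `NA` and `NaN` (case-insensitive); any other non-numeric
#' cell is an error naming the offending row and column, so dirty data
#' fails loudly instead of being silently dropped.
#'
#' @param path Path to the CSV file.
#' @param label_col Name of the label column. Default `"status"`.
#' @param id_col Optional name of a row-identifier column; `NULL` for none.
#' @return A tibble with numeric feature columns, an integer label column,
#'   and (if present) a `.row_id` character column. Row order is preserved.
#' @export
read_feature_table <- function(path, label_col = "status", id_col = "name") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  na.strings = character())
  if (!label_col %in% names(raw)) {
    abort(sprintf("Label column '%s' not found in %s.", label_col, path))
  }
  out <- tibble::new_tibble(vector("list", 0), nrow = nrow(raw))
  if (!is.null(id_col) && id_col %in% names(raw)) {
    out$.row_id <- as.character(raw[[id_col]])
    raw[[id_col]] <- NULL
  }
  missing_token <- function(x) trimws(tolower(x)) %in% c("", "na", "nan")
  for (col in setdiff(names(raw), label_col)) {
    x <- raw[[col]]
    miss <- missing_token(x)
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!miss & is.na(val))
    if (length(bad)) {
      abort(sprintf("Non-numeric value '%s' at row %d, column '%s'.",
                    x[bad[1]], bad[1], col))
    }
    val[miss] <- NA_real_
    out[[col]] <- val
  }
  lab <- suppressWarnings(as.integer(raw[[label_col]]))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L))) {
    abort(sprintf("Label column '%s' must contain only 0 and 1.", label_col))
  }
  out[[label_col]] <- lab
  out
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: numeric cells are written with full
#' double precision (17 significant digits) so a write/read round trip
#' reproduces values bit-for-bit; missing cells are written as `NA`.
#'
#' @param data Feature table.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  out <- as.data.frame(data, check.names = FALSE)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           sprintf("%.17g", out[[col]]))
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(data)
}

#' Split a table into training / validation / test partitions
#'
#' Adds a `.split` column assigning every row to `"train"`, `"validation"`
#' or `"test"`. The default 60/20/20 split is stratified by label: within
#' each class, training takes `floor(frac * n)` rows, validation takes its
#' floor, and test takes the remainder, so counts are reproducible and the
#' class ratio is preserved to within one row per partition. Assignment is
#' deterministic under `seed`; row order is preserved.
#'
#' @param data Feature table with a label column.
#' @param train_frac,val_frac,test_frac Partition fractions, each in (0,1),
#'   summing to 1. Defaults 0.6 / 0.2 / 0.2.
#' @param seed Integer seed for the within-stratum shuffle.
#' @param stratified Stratify by label? Default `TRUE`.
#' @param label_col Label column name.
#' @return `data` with an added `.split` factor column.
#' @seealso [partition()] to extract one partition.
#' @export
split_dataset <- function(data, train_frac = 0.6, val_frac = 0.2,
                          test_frac = 0.2, seed = 1, stratified = TRUE,
                          label_col = "status") {
  check_feature_table(data, label_col)
  fr <- c(train_frac, val_frac, test_frac)
  if (any(fr <= 0) || any(fr >= 1)) abort("Each split fraction must be in (0, 1).")
  if (abs(sum(fr) - 1) > 1e-9) abort("Split fractions must sum to 1.")
  n <- nrow(data)
  if (stratified && length(unique(data[[label_col]])) < 2) {
    abort("Both classes must be present for a stratified split.")
  }
  strata <- if (stratified) data[[label_col]] else rep(0L, n)
  assign <- character(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  for (s in sort(unique(strata))) {
    idx <- which(strata == s)
    m <- length(idx)
    n_tr <- floor(train_frac * m)
    n_va <- floor(val_frac * m)
    if (stratified && (n_tr < 1 || n_va < 1 || m - n_tr - n_va < 1)) {
      abort(sprintf("Class %s has too few rows (%d) to appear in every partition.", s, m))
    }
    ord <- sample(idx)
    assign[ord[seq_len(n_tr)]] <- "train"
    assign[ord[n_tr + seq_len(n_va)]] <- "validation"
    assign[ord[(n_tr + n_va + 1):m]] <- "test"
  }
  data$.split <- factor(assign, levels = c("train", "validation", "test"))
  data
}

#' Extract one partition from a split table
#'
#' @param data A table with a `.split` column from [split_dataset()].
#' @param which One of `"train"`, `"validation"`, `"test"`.
#' @return The rows of that partition, `.split` column dropped.
#' @export
partition <- function(data, which = c("train", "validation", "test")) {
  which <- match.arg(which)
  if (!".split" %in% names(data)) abort("`data` has no `.split` column; call split_dataset() first.")
  out <- data[data$.split == which, , drop = FALSE]
  out$.split <- NULL
  out
}
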