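make_tab <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  tibble::as_tibble(c(cols, list(status = rep(c(0L, 1L), length.out = n))))
}

test_that("column statistics use population SD over present records", {
  tab <- make_tab(a = c(2, 4, 6), b = c(5, 5, 5), c = c(1, NA, 3))
  st <- column_stats(tab)
  expect_equal(st$mean[st$feature == "a"], 4)
  expect_equal(st$sd[st$feature == "a"], sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(st$sd[st$feature == "a"], oracle_pop_sd(c(2, 4, 6)))
  expect_equal(st$mean[st$feature == "b"], 5)
  expect_equal(st$sd[st$feature == "b"], 0)
  expect_equal(st$mean[st$feature == "c"], 2)  # over the 2 present records
  expect_equal(st$n_present[st$feature == "c"], 2)
  all_na <- make_tab(a = c(NA_real_, NA_real_))
  expect_error(column_stats(all_na), "no present values")
})

test_that("z-scoring standardizes to mean 0 / SD 1 and centres constants", {
  tab <- make_tab(a = c(2, 4, 6), b = c(5, 5, 5))
  z <- zscore_transform(tab)
  expect_equal(mean(z$a), 0, tolerance = 1e-12)
  expect_equal(oracle_pop_sd(z$a), 1, tolerance = 1e-12)
  expect_equal(z$b, c(0, 0, 0))          # sd = 0 branch: value minus mean
  expect_equal(z$a[2], 0)                # value at the mean maps to 0
  # missing stays missing
  zm <- zscore_transform(make_tab(a = c(1, NA, 3), b = c(0, 1, 2)))
  expect_true(is.na(zm$a[2]))
  # mismatched stats are a contract error
  st <- column_stats(tab)
  expect_error(zscore_transform(make_tab(x = 1:3), st), "do not match")
})

test_that("cleaning is the identity on clean in-range data", {
  tab <- make_tab(a = c(1, 2, 3, 4), b = c(0.1, 0.2, 0.3, 0.4))
  out <- clean_records(tab)
  expect_equal(as.data.frame(out), as.data.frame(tab), ignore_attr = TRUE)
  expect_equal(nrow(attr(out, "dropped")), 0)
})

test_that("an extreme value drops exactly its row with reason 'irrelevant'", {
  tab <- make_tab(a = c(rnorm(30, sd = 0.1), 50), b = rep(1:31 / 31))
  out <- clean_records(tab, z_cutoff = 4)
  dropped <- attr(out, "dropped")
  expect_equal(nrow(out), 30)
  expect_equal(dropped$row, 31L)
  expect_equal(dropped$reason, "irrelevant")
})

test_that("mean imputation fills a missing cell with the present-record mean", {
  tab <- make_tab(a = c(1, NA, 3), b = c(0, 0.5, 1))
  out <- clean_records(tab, max_missing = 0.5)
  expect_equal(out$a[2], 2)
  expect_false(anyNA(out))
  # drop_row policy removes any row with a missing cell instead
  out2 <- clean_records(tab, policy = "drop_row")
  expect_equal(nrow(out2), 2)
  expect_equal(attr(out2, "dropped")$reason, "missing")
})

test_that("cleaning is idempotent", {
  set.seed(1)
  tab <- make_tab(a = c(rnorm(50), 8, -9), b = c(rnorm(51), 12))
  once <- clean_records(tab)
  twice <- clean_records(once)
  expect_equal(as.data.frame(twice), as.data.frame(once), ignore_attr = TRUE)
  expect_equal(nrow(attr(twice, "dropped")), 0)
})

test_that("min-max maps z-scores onto [0,1] with guarded constants", {
  z <- make_tab(a = c(-1.2247, 0, 1.2247), b = c(2, 2, 2))
  out <- minmax_normalize(z)
  expect_equal(out$a, c(0, 0.5, 1), tolerance = 1e-12)
  expect_equal(out$b, c(0, 0, 0))
  tab <- generate_pd_dataset(n_rows = 60, n_informative = 2, n_noise = 3, seed = 2)
  pre <- preprocess(tab)
  for (f in setdiff(names(pre), "status")) {
    expect_equal(min(pre[[f]]), 0)
    expect_equal(max(pre[[f]]), 1)
  }
})

test_that("preprocessing is location-scale invariant per feature", {
  tab <- generate_pd_dataset(n_rows = 80, n_informative = 2, n_noise = 2, seed = 3)
  shifted <- tab
  feats <- setdiff(names(tab), "status")
  for (f in feats) shifted[[f]] <- 7.5 * shifted[[f]] - 3
  a <- preprocess(tab)
  b <- preprocess(shifted)
  for (f in feats) expect_equal(b[[f]], a[[f]], tolerance = 1e-10)
})

test_that("frozen statistics transform new data without leakage or drops", {
  tab <- generate_pd_dataset(n_rows = 120, n_informative = 2, n_noise = 2,
                             missing_rate = 0.05, seed = 4)
  sp <- split_dataset(tab, seed = 4)
  pre_train <- preprocess(partition(sp, "train"))
  stats <- attr(pre_train, "stats")
  pre_test <- preprocess(partition(sp, "test"), stats = stats)
  expect_equal(nrow(pre_test), nrow(partition(sp, "test")))  # no rows dropped
  m <- as.matrix(pre_test[setdiff(names(pre_test), "status")])
  expect_true(all(m >= 0 & m <= 1))
  expect_false(anyNA(m))
})
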