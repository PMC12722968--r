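test_that("class-split statistics are exact per-class arithmetic", {
  tab <- tibble::tibble(f = c(0, 0.2, 0.8, 1.0), g = c(1, 1, 1, 1),
                        status = c(0L, 0L, 1L, 1L))
  st <- class_split_stats(tab)
  expect_equal(st$mean0[st$feature == "f"], 0.1)
  expect_equal(st$mean1[st$feature == "f"], 0.9)
  expect_equal(st$mean0[st$feature == "g"] - st$mean1[st$feature == "g"], 0)
  expect_equal(st$n0 + st$n1, rep(nrow(tab), 2))
  expect_error(class_split_stats(dplyr::filter(tab, status == 0)),
               "at least 2 rows")
})

test_that("the separation statistic matches an independent oracle on the fixture", {
  pre <- preprocess(make_worked_toy())
  w <- dasr_weights(pre)
  for (f in w$feature) {
    expect_equal(w$b_a[w$feature == f], oracle_std_diff(pre[[f]], pre$status),
                 tolerance = 1e-12, label = f)
  }
})

test_that("weights normalize, preserve ratios and flag non-separating features", {
  st <- tibble::tibble(feature = c("x", "y"), n0 = c(10L, 10L), n1 = c(10L, 10L),
                       mean0 = c(0, 0), mean1 = c(0.3, 0.1),
                       var0 = c(0.01, 0.01), var1 = c(0.01, 0.01))
  w <- dasr_weights(st)
  expect_equal(w$w_g, c(0.75, 0.25))           # b_a in ratio 3:1
  expect_equal(sum(w$w_g), 1, tolerance = 1e-12)
  # a feature identical across classes gets weight 0 when another separates
  st2 <- st; st2$mean1[2] <- 0
  w2 <- dasr_weights(st2)
  expect_equal(w2$b_a[2], 0)
  expect_equal(w2$w_g, c(1, 0))
  # nothing separates: uniform fallback with a warning
  st3 <- st; st3$mean1 <- c(0, 0)
  expect_warning(w3 <- dasr_weights(st3), "uniform")
  expect_equal(w3$w_g, c(0.5, 0.5))
})

test_that("the finest-feature score mixes weight and error rate as stated", {
  st <- tibble::tibble(feature = c("x", "y"), n0 = c(5L, 5L), n1 = c(5L, 5L),
                       mean0 = c(0, 0), mean1 = c(0.3, 0.1),
                       var0 = c(0.01, 0.01), var1 = c(0.01, 0.01))
  w <- dasr_weights(st, e_rate = 0.1)
  expect_equal(w$f2, w$w_g * 0.9 + (1 - w$w_g) * 0.1 / 2, tolerance = 1e-12)
  expect_error(dasr_weights(st, e_rate = 1), "e_rate")
})

test_that("weights are equivariant under feature permutation", {
  pre <- preprocess(generate_pd_dataset(n_rows = 100, n_informative = 3,
                                        n_noise = 4, seed = 5))
  w1 <- dasr_weights(pre)
  perm <- pre[, c(sample(setdiff(names(pre), "status")), "status")]
  w2 <- dasr_weights(perm)
  w2 <- w2[match(w1$feature, w2$feature), ]
  expect_equal(w2$w_g, w1$w_g, tolerance = 1e-12)
})

test_that("increasing mean separation never decreases a feature's weight", {
  base <- tibble::tibble(feature = c("x", "y", "z"), n0 = 20L, n1 = 20L,
                         mean0 = 0, mean1 = c(0.1, 0.2, 0.3),
                         var0 = 0.02, var1 = 0.02)
  w_before <- dasr_weights(base)$w_g[1]
  grown <- base; grown$mean1[1] <- 0.25
  w_after <- dasr_weights(grown)$w_g[1]
  expect_gt(w_after, w_before)
})

test_that("planted informative features out-weigh every noise feature", {
  wins <- vapply(1:10, function(s) {
    tab <- generate_pd_dataset(n_rows = 400, n_informative = 1, n_noise = 10,
                               effect_size = 2, seed = s)
    w <- dasr_weights(preprocess(tab))
    inf <- informative_features(tab)
    w$w_g[w$feature == inf] == max(w$w_g)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("both-variances-zero guard avoids 0/0", {
  st <- tibble::tibble(feature = c("x", "y"), n0 = 3L, n1 = 3L,
                       mean0 = c(0, 0), mean1 = c(1, 0.5),
                       var0 = 0, var1 = 0)
  w <- dasr_weights(st)
  expect_true(all(is.finite(w$w_g)))
  expect_equal(w$w_g, c(2 / 3, 1 / 3))   # ratios of the guarded b_a survive
})
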