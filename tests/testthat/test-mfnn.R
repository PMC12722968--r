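test_that("Gaussian membership matches its closed forms", {
  expect_equal(fuzzy_membership(0.4, 0.4, 0.1), 1)
  expect_equal(fuzzy_membership(0.5, 0.4, 0.1), exp(-1 / 2))
  expect_equal(fuzzy_membership(0.5, 0.4, 0.1), 0.606531, tolerance = 1e-6)
  # symmetric around the center
  expect_equal(fuzzy_membership(0.7, 0.5, 0.2), fuzzy_membership(0.3, 0.5, 0.2))
  expect_error(fuzzy_membership(0, 0, 0), "width")
})

test_that("initialization seeds rules near the class centroids, deterministically", {
  pre <- preprocess(make_worked_toy())
  X <- as.matrix(pre[c("PPE", "spread1")])
  y <- pre$status
  m <- pdfuzz:::mfnn_init(X, y, c("PPE", "spread1"), 2, 0.05, "product", 1)
  cent0 <- colMeans(X[y == 0, ]); cent1 <- colMeans(X[y == 1, ])
  expect_lt(max(abs(m$centers[1, ] - cent0)), 0.15)
  expect_lt(max(abs(m$centers[2, ] - cent1)), 0.15)
  expect_true(all(m$widths >= 0.05))
  m2 <- pdfuzz:::mfnn_init(X, y, c("PPE", "spread1"), 2, 0.05, "product", 1)
  expect_identical(m, m2)
  expect_error(pdfuzz:::mfnn_init(X, y, c("PPE", "spread1"), 100, 0.05,
                                  "product", 1), "distinct training rows")
})

test_that("the forward pass matches a straight-line oracle and normalizes", {
  rs <- random_small_model(seed = 21, n_rules = 3, d = 2)
  fw <- mfnn_forward(rs$model, rs$X)
  for (i in seq_len(nrow(rs$X))) {
    expect_equal(unname(fw$prob[i, ]), oracle_forward(rs$model, rs$X[i, ]),
                 tolerance = 1e-10)
  }
  expect_equal(unname(rowSums(fw$prob)), rep(1, nrow(rs$X)), tolerance = 1e-12)
  expect_true(all(fw$firing > 0 & fw$firing <= 1))
  expect_error(mfnn_forward(rs$model, rs$X[, 1, drop = FALSE]), "arity")
})

test_that("zeroed consequents give an indifferent 50/50 classifier", {
  rs <- random_small_model(seed = 3)
  m <- rs$model
  m$p[] <- 0; m$q[] <- 0; m$v0 <- c(0, 0)
  fw <- mfnn_forward(m, rs$X)
  expect_equal(unname(fw$prob), matrix(0.5, nrow(rs$X), 2), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  rs <- random_small_model(seed = 42, n_rules = 2, d = 2)
  gr <- mfnn_gradients(rs$model, rs$X, rs$y)
  for (nm in c("centers", "widths", "p", "q", "V", "v0")) {
    fd <- fd_gradient(rs$model, rs$X, rs$y, nm)
    rel <- max(abs(as.vector(gr[[nm]]) - as.vector(fd)) /
                 pmax(abs(as.vector(fd)), 1e-8))
    expect_lt(rel, 1e-4, label = nm)
  }
})

test_that("the momentum update follows hand arithmetic", {
  st <- new_train_state(learning_rate = 0.5, momentum = 0.5)
  # quadratic loss L = w^2, gradient 2w, starting at w = 1
  up1 <- update_weights(st, 1, 2)
  expect_equal(up1$weight, 0)            # -0.5*2 = -1
  up2 <- update_weights(up1$state, up1$weight, 0)
  expect_equal(up2$weight, -0.5)         # momentum carries -1 * 0.5
  # zero gradient with no history is a fixed point
  st2 <- new_train_state(0.6, 0.9)
  expect_equal(update_weights(st2, 3.2, 0)$weight, 3.2)
  expect_error(update_weights(st2, 1, NaN), "Non-finite")
})

test_that("learning rates in the supported 0.4-0.8 band pass silently, others warn", {
  pre <- preprocess(make_worked_toy())
  expect_no_warning(mfnn(pre, n_rules = 2, epochs = 2, learning_rate = 0.4, seed = 1))
  expect_no_warning(mfnn(pre, n_rules = 2, epochs = 2, learning_rate = 0.8, seed = 1))
  expect_warning(mfnn(pre, n_rules = 2, epochs = 2, learning_rate = 0.2, seed = 1),
                 "0.4-0.8")
  expect_error(mfnn(pre, n_rules = 2, epochs = 2, learning_rate = 1.5, seed = 1),
               "learning_rate")
})

test_that("one epoch of training does not increase the fixture loss", {
  pre <- preprocess(make_worked_toy())
  X <- as.matrix(pre[setdiff(names(pre), "status")])
  y <- pre$status
  init <- pdfuzz:::mfnn_init(X, y, colnames(X), 2, 0.05, "product", 1)
  loss0 <- mfnn_loss(init, X, y)
  fit <- mfnn(pre, n_rules = 2, epochs = 1, seed = 1)
  expect_lte(mfnn_loss(fit, X, y), loss0 + 1e-12)
})

test_that("training solves separable one-dimensional data", {
  accs <- vapply(1:3, function(s) {
    tab <- generate_pd_dataset(n_rows = 200, n_informative = 1, n_noise = 0,
                               effect_size = 5, seed = s,
                               feature_name_style = "generic")
    pre <- preprocess(tab)
    fit <- mfnn(pre, n_rules = 2, epochs = 200, seed = s)
    mean(predict(fit, pre, type = "class") == pre$status)
  }, 0)
  expect_true(all(accs >= 0.95))
})

test_that("training is invariant to row permutation under full batch", {
  tab <- generate_pd_dataset(n_rows = 60, n_informative = 2, n_noise = 1,
                             effect_size = 2, seed = 6)
  pre <- preprocess(tab)
  fit1 <- mfnn(pre, n_rules = 2, epochs = 20, seed = 6)
  set.seed(99)
  perm <- pre[sample(nrow(pre)), ]
  fit2 <- mfnn(perm, n_rules = 2, epochs = 20, seed = 6)
  expect_equal(fit2$centers, fit1$centers, tolerance = 1e-9)
  expect_equal(fit2$q, fit1$q, tolerance = 1e-9)
})

test_that("risk stratification is the stated piecewise map", {
  r <- assign_risk(c(0, 0.2, 0.33, 0.5, 0.66, 0.9, 1))
  expect_equal(as.character(r$risk_class),
               c("low", "low", "medium", "medium", "high", "high", "high"))
  expect_equal(r$label, as.integer(r$p_pd >= 0.5))
  expect_error(assign_risk(0.5, thresholds = c(0.7, 0.3)), "increasing")
  expect_error(assign_risk(1.2), "prob")
})

test_that("tidy, glance, augment and autoplot work on a fitted model", {
  pre <- preprocess(make_worked_toy())
  fit <- mfnn(pre, n_rules = 2, epochs = 10, seed = 1)
  td <- tidy(fit)
  expect_true(all(c("center", "width", "consequent", "bias", "class_weight") %in%
                    td$term))
  expect_equal(sum(td$term == "center"), 2 * 4)
  gl <- glance(fit)
  expect_equal(gl$n_rules, 2)
  expect_lte(gl$epochs_run, 10)
  au <- augment(fit, pre)
  expect_true(all(c(".p_pd", ".pred_label", ".risk_class") %in% names(au)))
  expect_s3_class(autoplot(fit), "ggplot")
})
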