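test_that("dataset splits are exact, stratified, disjoint and reproducible", {
  segs <- lapply(1:100, function(i) list(label = (i <= 50) * 1L, id = i))
  sp <- split_dataset(segs, ratios = c(0.8, 0.1, 0.1), seed = 7)
  expect_length(sp$train, 80)
  expect_length(sp$test, 10)
  expect_length(sp$validation, 10)
  idx_all <- sort(unname(unlist(sp$indices)))
  expect_equal(idx_all, 1:100)
  # class balance within one sample of 50% in each partition
  for (part in c("train", "test", "validation")) {
    labs <- vapply(sp[[part]], `[[`, numeric(1), "label")
    expect_lte(abs(sum(labs) - length(labs) / 2), 1)
  }
  sp2 <- split_dataset(segs, ratios = c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(sp$indices, sp2$indices)
  sp3 <- split_dataset(segs, ratios = c(0.8, 0.1, 0.1), seed = 8)
  expect_false(identical(sp$indices, sp3$indices))
  one_class <- lapply(1:10, function(i) list(label = 1L))
  expect_error(split_dataset(one_class), "per class")
})

test_that("accuracy matches hand arithmetic and its invariants", {
  expect_equal(accuracy(list(TP = 2, TN = 3, P = 4, N = 4)), 0.625)
  expect_equal(accuracy(list(TP = 10, TN = 5, P = 10, N = 5)), 1)
  expect_equal(accuracy(list(TP = 0, TN = 0, P = 3, N = 2)), 0)
  expect_error(accuracy(list(TP = 0, TN = 0, P = 0, N = 0)), "undefined")
  withr::local_seed(41)
  for (i in 1:20) {
    truth <- sample(0:1, 30, replace = TRUE)
    pred <- sample(0:1, 30, replace = TRUE)
    a <- accuracy(confusion_counts(truth, pred))
    expect_gte(a, 0)
    expect_lte(a, 1)
    # swapping class roles leaves accuracy unchanged
    expect_equal(accuracy(confusion_counts(1 - truth, 1 - pred)), a)
  }
})

test_that("training is reproducible and learns a separable toy problem", {
  toy <- toy_features(40, tl = 8, n_coeffs = 4, seed = 42)
  m1 <- build_baseline(baseline_spec("cnn", c(8, 4), width = 8), seed = 5)
  m2 <- build_baseline(baseline_spec("cnn", c(8, 4), width = 8), seed = 5)
  ctl <- train_control(lr = 5e-3, epochs = 20, batch_size = 8,
                       patience = Inf)
  fit1 <- train_model(m1, toy$x, toy$y, control = ctl, seed = 6)
  fit2 <- train_model(m2, toy$x, toy$y, control = ctl, seed = 6)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_equal(fit1$history, fit2$history)
  expect_gte(fit1$history$train_accuracy[20], 0.95)
  # label shuffling destroys generalisation: validation stays near chance
  withr::local_seed(43)
  ysh <- sample(toy$y)
  val <- toy_features(40, tl = 8, n_coeffs = 4, seed = 44)
  m3 <- build_baseline(baseline_spec("cnn", c(8, 4), width = 8), seed = 5)
  fit3 <- train_model(m3, toy$x, ysh, val$x, sample(val$y),
                      control = train_control(epochs = 8, batch_size = 8,
                                              patience = Inf), seed = 6)
  last <- fit3$history$val_accuracy[nrow(fit3$history)]
  expect_gte(last, 0.25)
  expect_lte(last, 0.75)
})

test_that("training errors out on divergence with diagnostics", {
  toy <- toy_features(16, tl = 4, n_coeffs = 2, seed = 45)
  m <- build_baseline(baseline_spec("cnn", c(4, 2), width = 4), seed = 1)
  m$params$conv1.W[] <- 1e160           # overflow cascades to the logits
  m$params$conv2.W[] <- 1e160
  expect_error(
    train_model(m, toy$x, toy$y,
                control = train_control(epochs = 1, batch_size = 8,
                                        patience = Inf), seed = 1),
    "non-finite")
})

test_that("the Mann-Whitney U statistic and exact p are correct", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p.value, perm_mwu_p(c(1, 2, 3), c(4, 5, 6)))
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 9 / 2)
  expect_equal(same$p.value, 1, tolerance = 0.05)
  withr::local_seed(46)
  # exact enumeration equals the full label-permutation oracle
  for (n in c(3, 5)) {
    for (rep in 1:5) {
      a <- rnorm(n)
      b <- rnorm(n) + runif(1, -1, 1)
      mw <- mann_whitney_u(a, b)
      expect_equal(mw$method, "exact")
      expect_equal(mw$p.value, perm_mwu_p(a, b), tolerance = 1e-12)
      # cross-check against the standard library implementation
      expect_equal(mw$p.value, stats::wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
      # U identity for tie-free data
      expect_equal(mw$U + mann_whitney_u(b, a)$U, n * n)
    }
  }
  expect_error(mann_whitney_u(c(1, 2), c(3, 4, 5)), "at least 3")
  # large / tied samples fall back to the corrected normal approximation
  big <- mann_whitney_u(rnorm(25), rnorm(25))
  expect_equal(big$method, "normal approximation")
  expect_gte(big$p.value, 0)
  expect_lte(big$p.value, 1)
})

test_that("significance labels mirror the reporting thresholds", {
  expect_equal(significance_label(0.5), "ns")
  expect_equal(significance_label(0.009), "**")
  expect_equal(significance_label(0.0009), "***")
  expect_equal(significance_label(0.00009), "****")
})

test_that("tidy and glance methods return well-formed tibbles", {
  toy <- toy_features(20, tl = 4, n_coeffs = 2, seed = 47)
  m <- build_baseline(baseline_spec("cnn", c(4, 2), width = 4), seed = 1)
  fit <- train_model(m, toy$x, toy$y,
                     control = train_control(epochs = 3, batch_size = 8,
                                             patience = Inf), seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(gl$family, "cnn")
  expect_equal(gl$epochs, 3)
  mw <- mann_whitney_u(1:3, 4:6)
  expect_equal(tidy(mw)$statistic, 0)
  expect_s3_class(autoplot(fit), "ggplot")
})
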