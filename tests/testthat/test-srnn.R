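test_that("forward pass yields normalized probabilities of the right shape", {
  spec <- srnn_spec(input_dim = 25, n_flank = 10, hidden_size = 8,
                    dense_sizes = 4, seed = 2)
  mod <- build_model(spec)
  withr::with_seed(1, x <- array(runif(5 * 21 * 25), dim = c(5, 21, 25)))
  p <- srnn_forward(mod$params, x)$p
  expect_equal(dim(p), c(5, 2))
  expect_equal(rowSums(p), rep(1, 5))
  expect_true(all(p > 0 & p < 1))
  # one-sample forward works and matches the batch
  p1 <- srnn_forward(mod$params, x[1, , , drop = FALSE])$p
  expect_equal(as.numeric(p1), as.numeric(p[1, ]), tolerance = 1e-6)
  # same seed gives identical initialization
  expect_identical(build_model(spec)$params, mod$params)
  expect_false(identical(
    build_model(srnn_spec(25, 10, 8, 4, seed = 3))$params, mod$params))
})

test_that("cross-entropy matches closed forms", {
  expect_lt(cross_entropy(1, 1 - 1e-9), 1e-6)
  expect_equal(cross_entropy(1, 0.5), log(2))
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_error(cross_entropy(c(1, 0), 0.5), "length")
})

test_that("penalties match hand-computed values and their properties", {
  expect_equal(l1_penalty(c(0.5, -0.5, 0)), 1)
  expect_equal(l1_penalty(rep(0, 10)), 0)
  w <- c(3, 4)
  g <- list(1:2)
  expect_equal(sgl_penalty(w, g, alpha = 1), sqrt(2) * 5, tolerance = 1e-9)
  expect_equal(sgl_penalty(w, g, alpha = 0), 7, tolerance = 1e-9)
  expect_equal(sgl_penalty(w, g, alpha = 0.5), 0.5 * sqrt(2) * 5 + 0.5 * 7,
               tolerance = 1e-9)
  expect_equal(sgl_penalty(w, g, alpha = 1, size_scaling = FALSE), 5)
  expect_error(sgl_penalty(w, list(1:2, 2), 0.5), "overlap")
  # homogeneity and alpha = 0 reduction over random draws
  withr::with_seed(99, {
    for (i in 1:100) {
      v <- rnorm(12)
      grp <- split(1:12, rep(1:3, each = 4))
      cc <- rnorm(1)
      expect_equal(l1_penalty(cc * v), abs(cc) * l1_penalty(v))
      expect_equal(sgl_penalty(cc * v, grp, 0.3),
                   abs(cc) * sgl_penalty(v, grp, 0.3))
      expect_equal(sgl_penalty(v, grp, 0), l1_penalty(v))
    }
  })
})

test_that("the objective decomposes into cross-entropy plus lambda R(W)", {
  withr::with_seed(5, x <- array(runif(6 * 5 * 22), dim = c(6, 5, 22)))
  y <- c(1, 0, 1, 1, 0, 0)
  withr::with_seed(7, {
    for (i in 1:20) {
      lam <- runif(1, 0, 2)
      spec <- quick_spec(reg_input = sample(c("l1", "sgl"), 1),
                         reg_hidden = sample(c("none", "l1", "sgl"), 1),
                         lambda = lam, seed = sample.int(1000, 1))
      mod <- build_model(spec)
      obj <- regularized_loss(mod, x, y)
      ce <- cross_entropy(y, srnn_forward(mod$params, x)$p[, 2])
      pen <- oglcnac:::model_penalty(mod$params, spec)
      expect_equal(obj - ce, lam * pen, tolerance = 1e-12)
    }
  })
  # lambda 0 equals the cross-entropy exactly; doubling lambda doubles the gap
  spec0 <- quick_spec(lambda = 0)
  mod0 <- build_model(spec0)
  expect_equal(regularized_loss(mod0, x, y),
               cross_entropy(y, srnn_forward(mod0$params, x)$p[, 2]))
  s1 <- quick_spec(reg_input = "sgl", lambda = 0.1)
  s2 <- quick_spec(reg_input = "sgl", lambda = 0.2)
  m1 <- build_model(s1); m2 <- build_model(s2)
  ce <- cross_entropy(y, srnn_forward(m1$params, x)$p[, 2])
  expect_equal(2 * (regularized_loss(m1, x, y) - ce),
               regularized_loss(m2, x, y) - ce, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a tiny model", {
  spec <- srnn_spec(input_dim = 3, n_flank = 1, hidden_size = 2,
                    dense_sizes = 2, reg_input = "sgl", reg_hidden = "sgl",
                    lambda = 0.05, alpha = 0.4, seed = 21)
  mod <- build_model(spec)
  withr::with_seed(31, {
    x <- array(runif(6 * 3 * 3), dim = c(6, 3, 3))
    y <- rep(c(0, 1), 3)
  })
  expect_lt(check_gradient(mod, x, y), 1e-4)
  # and with plain L1 / no regularization
  for (reg in c("none", "l1")) {
    sp <- srnn_spec(3, 1, 2, 2, reg_input = reg, reg_hidden = reg,
                    lambda = if (reg == "none") 0 else 0.1, seed = 22)
    expect_lt(check_gradient(build_model(sp), x, y), 1e-4)
  }
})

test_that("training solves a separable problem and is reproducible", {
  ds <- separable_dataset(n = 400, seed = 8)
  parts <- split_train_test(ds, 0.2, seed = 8)
  spec <- quick_spec(seed = 8)
  fit <- fit_site_model(parts$train, spec, seed = 8)
  expect_lte(fit$stopped_epoch, 50)
  train_pred <- classify(predict_proba(fit, parts$train))
  expect_equal(metrics(confusion_counts(parts$train$labels, train_pred))$f1, 1)
  expect_equal(evaluate_model(fit, parts$test)$f1, 1)
  # identical spec/seed/data reproduce the training log and parameters
  fit2 <- fit_site_model(parts$train, spec, seed = 8)
  expect_identical(fit$training_log, fit2$training_log)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$stopped_epoch, fit2$stopped_epoch)
})

test_that("prediction is deterministic and batching-invariant", {
  ds <- separable_dataset(n = 50, seed = 3)
  fit <- build_model(quick_spec(seed = 3))
  p_all <- predict_proba(fit, ds$x)
  expect_true(all(p_all >= 0 & p_all <= 1))
  p_single <- vapply(seq_len(50), function(i)
    predict_proba(fit, ds$x[i, , , drop = FALSE]), numeric(1))
  expect_equal(p_single, p_all, tolerance = 1e-6)
  p_dup <- predict_proba(fit, ds$x[c(1, 1), , ])
  expect_identical(p_dup[1], p_dup[2])
  expect_equal(p_dup[1], p_all[1], tolerance = 1e-6)
})

test_that("thresholding is monotone in the threshold", {
  withr::with_seed(4, p <- runif(200))
  expect_equal(classify(0.6, 0.5), 1L)
  expect_equal(classify(0.6, 0.9), 0L)
  n_pos <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                  function(th) sum(classify(p, th)), 0L)
  expect_true(all(diff(n_pos) <= 0))
})

test_that("a heavy L1 penalty drives most input groups to zero norm", {
  ds <- make_planted_dataset(300, n_features = 10, informative = 1:2,
                             effect_size = 3, positive_fraction = 0.5,
                             n_flank = 2, seed = 4)
  parts <- split_train_test(ds, 0.2, seed = 4)
  spec <- srnn_spec(input_dim = 30, n_flank = 2, hidden_size = 6,
                    dense_sizes = 4, reg_input = "l1", lambda = 10,
                    max_epochs = 80, patience = 80, batch_size = 32, seed = 4)
  fit <- fit_site_model(parts$train, spec, seed = 4, restore_best = FALSE)
  norms <- sqrt(rowSums(fit$params$Wx^2))
  expect_gt(mean(norms < 1e-3), 0.5)
})

test_that("input-group sparsity is non-decreasing in lambda", {
  ds <- make_planted_dataset(300, n_features = 10, informative = 1:2,
                             effect_size = 3, positive_fraction = 0.5,
                             n_flank = 2, seed = 4)
  parts <- split_train_test(ds, 0.2, seed = 4)
  n_small <- vapply(c(0, 1e-4, 1e-3, 1e-2, 1e-1), function(lam) {
    spec <- srnn_spec(input_dim = 30, n_flank = 2, hidden_size = 6,
                      dense_sizes = 4, reg_input = "l1", lambda = lam,
                      max_epochs = 40, patience = 40, batch_size = 32,
                      seed = 4)
    fit <- fit_site_model(parts$train, spec, seed = 4, restore_best = FALSE)
    sum(sqrt(rowSums(fit$params$Wx^2)) < 1e-3)
  }, 0L)
  expect_true(all(diff(n_small) >= 0))
})
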