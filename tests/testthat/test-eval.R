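test_that("confusion counts tally the 2x2 table", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cc), c(TP = 1, FP = 1, TN = 1, FN = 1))
  truth <- withr::with_seed(1, rbinom(50, 1, 0.3))
  same <- confusion_counts(truth, truth)
  expect_equal(same$FP + same$FN, 0)
  inv <- confusion_counts(truth, 1 - truth)
  expect_equal(inv$TP + inv$TN, 0)
  expect_error(confusion_counts(c(1, 0), 1), "length")
})

test_that("metrics follow the standard formulas with a 0/0 -> 0 convention", {
  m <- metrics(tibble::tibble(TP = 2, FP = 1, FN = 1, TN = 0))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  m0 <- metrics(tibble::tibble(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_equal(c(m0$precision, m0$recall, m0$f1), c(0, 0, 0))
  expect_equal(m0$accuracy, 0.5)
  m1 <- metrics(tibble::tibble(TP = 1, TN = 25, FP = 0, FN = 0))
  expect_equal(c(m1$accuracy, m1$f1), c(1, 1))
  expect_error(metrics(tibble::tibble(TP = 0, FP = 0, FN = 0, TN = 0)))
})

test_that("metrics agree with an independent reference on random tables", {
  skip_if_not_installed("caret")
  withr::with_seed(2024, {
    for (i in 1:1000) {
      counts <- as.list(setNames(rmultinom(1, sample(4:60, 1),
                                           runif(4, 0.05, 1))[, 1],
                                 c("TP", "FP", "TN", "FN")))
      truth <- c(rep(1, counts$TP), rep(0, counts$FP),
                 rep(0, counts$TN), rep(1, counts$FN))
      pred <- c(rep(1, counts$TP), rep(1, counts$FP),
                rep(0, counts$TN), rep(0, counts$FN))
      m <- metrics(confusion_counts(truth, pred))
      fl <- factor(truth, levels = c(1, 0))
      fp <- factor(pred, levels = c(1, 0))
      expect_equal(m$accuracy, mean(truth == pred))
      ref_p <- caret::precision(fp, fl, relevant = "1")
      ref_r <- caret::recall(fp, fl, relevant = "1")
      ref_f <- caret::F_meas(fp, fl, relevant = "1")
      if (!is.na(ref_p)) expect_equal(m$precision, ref_p)
      if (!is.na(ref_r)) expect_equal(m$recall, ref_r)
      if (!is.na(ref_f)) expect_equal(m$f1, ref_f)
      # literal F1 bounds
      expect_gte(m$f1, 0); expect_lte(m$f1, 1)
      expect_equal(m$f1 == 0, counts$TP == 0)
      if (m$precision == m$recall) expect_equal(m$f1, m$precision)
    }
  })
})

test_that("feature importance reflects input-group norms", {
  spec <- quick_spec(seed = 12)
  mod <- build_model(spec, feature_names = c(paste0("aa_", AA_ALPHABET),
                                             "envA", "envB"))
  # zeroed group scores 0 and ranks last
  mod$params$Wx[21, ] <- 0
  imp <- feature_importance(mod)
  expect_equal(imp$score[imp$feature == "envA"], 0)
  expect_equal(imp$feature[nrow(imp)], "envA")
  expect_true(all(diff(imp$score) <= 0))
  # swapping two features' input columns swaps their scores exactly
  mod2 <- mod
  mod2$params$Wx[c(21, 22), ] <- mod2$params$Wx[c(22, 21), ]
  imp2 <- feature_importance(mod2)
  expect_equal(imp2$score[imp2$feature == "envA"],
               imp$score[imp$feature == "envB"])
  expect_equal(imp2$score[imp2$feature == "envB"],
               imp$score[imp$feature == "envA"])
})

test_that("importance ranking is stable across identical refits", {
  ds <- separable_dataset(n = 200, seed = 15)
  spec <- quick_spec(reg_input = "sgl", lambda = 1e-3, max_epochs = 15,
                     seed = 15)
  fit1 <- fit_site_model(ds, spec, seed = 15)
  fit2 <- fit_site_model(ds, spec, seed = 15)
  expect_identical(feature_importance(fit1), feature_importance(fit2))
  expect_identical(tidy(fit1), feature_importance(fit1))
})

test_that("top-fraction selection uses the ceiling", {
  ranking <- tibble::tibble(feature = sprintf("f%03d", 1:498),
                            score = seq(498, 1), rank = 1:498)
  expect_length(select_top_fraction(ranking, 0.2), 100)
  expect_length(select_top_fraction(ranking, 1), 498)
  small <- ranking[1:10, ]
  expect_length(select_top_fraction(small, 0.5), 5)
  expect_equal(select_top_fraction(small, 0.5), sprintf("f%03d", 1:5))
  expect_error(select_top_fraction(ranking[0, ], 0.5), "empty")
})

test_that("mean ratio follows the signed convention", {
  expect_equal(mean_ratio(2, 1)$ratio, 2)
  expect_equal(mean_ratio(1, 2)$ratio, -2)
  expect_equal(mean_ratio(3, 3)$ratio, 1)
  expect_equal(mean_ratio(0, 0)$ratio, 1)
  inf1 <- mean_ratio(1, 0)
  expect_equal(inf1$ratio, Inf); expect_equal(inf1$flag, "pos_inf")
  inf2 <- mean_ratio(0, 1)
  expect_equal(inf2$ratio, -Inf); expect_equal(inf2$flag, "neg_inf")
  # antisymmetry over random nonzero draws
  withr::with_seed(77, {
    for (i in 1:100) {
      ab <- abs(rnorm(2)) + 0.01
      if (ab[1] == ab[2]) next
      expect_equal(mean_ratio(ab[1], ab[2])$ratio,
                   -mean_ratio(ab[2], ab[1])$ratio)
      expect_gte(abs(mean_ratio(ab[1], ab[2])$ratio), 1)
    }
  })
})

test_that("ratio profiles localize a planted subsite effect", {
  # multiplicative x2 elevation: shift by the folded-normal mean
  eff <- sqrt(2 / pi)
  ds <- make_planted_dataset(2000, n_features = 6, informative = 3,
                             effect_size = eff, positive_fraction = 0.5,
                             n_flank = 10, label_position = -2, seed = 31)
  prof <- ratio_profile(ds, "env03")
  expect_equal(prof$position, -10:10)
  peak <- prof$position[which.max(abs(prof$ratio))]
  expect_equal(peak, -2)
  expect_equal(prof$ratio[prof$position == -2], 2, tolerance = 0.1)
  off <- prof$ratio[prof$position != -2]
  expect_true(all(abs(off) < 1.2))
  # an uninformative feature stays flat
  flat <- ratio_profile(ds, "env01")
  expect_true(all(abs(flat$ratio) < 1.2))
  # identical classes give exactly +1 everywhere
  ds0 <- ds
  ds0$x_raw[ds0$labels == 1, , ] <- ds0$x_raw[ds0$labels == 0, , ]
  expect_true(all(ratio_profile(ds0, "env03")$ratio == 1))
  # swapping labels negates every ratio, magnitudes preserved
  dsw <- ds
  dsw$labels <- 1L - dsw$labels
  profw <- ratio_profile(dsw, "env03")
  expect_equal(profw$ratio, -prof$ratio)
  expect_error(ratio_profile(ds, "nope"), "unknown feature")
})

test_that("Monte-Carlo CV reports per-repeat metrics and their summary", {
  ds <- separable_dataset(n = 250, seed = 40)
  spec <- quick_spec(max_epochs = 40, learning_rate = 0.01, seed = 40)
  cv <- monte_carlo_cv(ds, spec, repeats = 3, seed = 40)
  expect_equal(nrow(cv$per_repeat), 3)
  f1s <- cv$per_repeat$f1
  mu <- cv$summary$mean[cv$summary$metric == "f1"]
  expect_gte(mu, min(f1s)); expect_lte(mu, max(f1s))
  # trivially separable positives give near-perfect mean F1
  expect_gt(mu, 0.9)
  # determinism under the base seed
  cv2 <- monte_carlo_cv(ds, spec, repeats = 3, seed = 40)
  expect_identical(cv$per_repeat, cv2$per_repeat)
  # tidiers
  expect_identical(tidy(cv), cv$per_repeat)
  expect_equal(glance(cv)$repeats, 3)
})
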