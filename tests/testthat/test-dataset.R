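test_that("scaler maps train data to [0,1] and clips unseen values", {
  tbl <- data.frame(a = c(2, 4, 6), b = c(5, 5, 5))
  bounds <- fit_scaler(tbl)
  scaled <- apply_scaler(tbl, bounds)
  expect_equal(scaled[, "a"], c(0, 0.5, 1))
  expect_equal(scaled[, "b"], c(0, 0, 0))  # constant feature -> 0
  test <- data.frame(a = c(-1, 10), b = c(7, 3))
  st <- apply_scaler(test, bounds)
  expect_equal(st[, "a"], c(0, 1))  # clipped
  expect_error(fit_scaler(data.frame(a = numeric(0))), "empty")
  # idempotence on the fit table: min 0, max 1 for non-constant features
  withr::with_seed(1, big <- data.frame(u = rnorm(50), v = runif(50)))
  sb <- apply_scaler(big, fit_scaler(big))
  expect_equal(unname(apply(sb, 2, min)), c(0, 0))
  expect_equal(unname(apply(sb, 2, max)), c(1, 1))
})

test_that("assemble_samples builds the expected shapes and zero pad rows", {
  seqs <- c(p1 = "MASTKVLDES", p2 = "GGSTPQRWYV")
  sites <- tibble::tibble(protein_id = c("p1", "p1", "p2"),
                          site = c(4L, 10L, 3L), label = c(1L, 0L, 1L))
  env <- dplyr::bind_rows(
    featurize_sites(make_toy_structure(seqs[["p1"]], id = "p1"),
                    seq_len(nchar(seqs[["p1"]]))),
    featurize_sites(make_toy_structure(seqs[["p2"]], id = "p2"),
                    seq_len(nchar(seqs[["p2"]]))))
  ds <- assemble_samples(sites, seqs, env, n_flank = 3)
  expect_s3_class(ds, "og_dataset")
  expect_equal(dim(ds$x), c(3, 7, 20 + ncol(env) - 2))
  expect_equal(ds$labels, c(1L, 0L, 1L))
  # site 10 of p1: window overhangs the C-terminus by 3 -> zero rows
  expect_equal(ds$meta$window[2], "LDES---")
  expect_equal(sum(ds$x[2, 5:7, ]), 0)
  # one-hot block of each non-pad position sums to 1
  onehot <- ds$x[1, , 1:20]
  expect_equal(rowSums(onehot), rep(1, 7))
  # determinism
  expect_identical(ds$x, assemble_samples(sites, seqs, env, n_flank = 3)$x)
  # unknown protein errors
  expect_error(assemble_samples(
    tibble::tibble(protein_id = "zz", site = 1L, label = 0L), seqs, env, 3),
    "no sequence")
})

test_that("train/test split is stratified, disjoint and reproducible", {
  ds <- make_planted_dataset(100, n_features = 4, positive_fraction = 0.2,
                             n_flank = 2, seed = 7)
  parts <- split_train_test(ds, test_fraction = 0.2, seed = 3)
  expect_equal(n_samples(parts$train), 80)
  expect_equal(n_samples(parts$test), 20)
  expect_equal(sum(parts$test$labels), 4)  # 20% of 20 positives
  expect_equal(sort(c(parts$train$meta$site, parts$test$meta$site)),
               1:100)
  parts2 <- split_train_test(ds, test_fraction = 0.2, seed = 3)
  expect_identical(parts$test$meta$site, parts2$test$meta$site)
  parts3 <- split_train_test(ds, test_fraction = 0.2, seed = 4)
  expect_false(identical(parts$test$meta$site, parts3$test$meta$site))
})

test_that("oversampling balances classes and preserves positive windows", {
  ds <- make_planted_dataset(104, n_features = 3, positive_fraction = 4 / 104,
                             n_flank = 2, seed = 5)
  expect_equal(sum(ds$labels), 4)
  bal <- oversample_positives(ds, seed = 1)
  expect_equal(sum(bal$labels == 1), sum(bal$labels == 0))
  # 4 pos / 100 neg: every positive appears exactly 25 times
  tab <- table(bal$meta$site[bal$labels == 1])
  expect_equal(as.integer(tab), rep(25L, 4))
  # non-integral ratio: 3 pos / 100 neg -> 33 copies each plus one extra
  ds3 <- dataset_subset(ds, c(which(ds$labels == 1)[1:3],
                              which(ds$labels == 0)))
  bal3 <- oversample_positives(ds3, seed = 2)
  tab3 <- table(bal3$meta$site[bal3$labels == 1])
  expect_equal(sort(as.integer(tab3)), c(33L, 33L, 34L))
  # already balanced -> unchanged
  even <- make_planted_dataset(40, n_features = 3, positive_fraction = 0.5,
                               n_flank = 2, seed = 6)
  expect_identical(oversample_positives(even, 1)$x, even$x)
})

test_that("k-fold partition is stratified with near-equal fold sizes", {
  ds <- make_planted_dataset(103, n_features = 3, positive_fraction = 0.25,
                             n_flank = 2, seed = 9)
  folds <- kfold_partition(ds, 5, seed = 2)
  expect_length(folds, 5)
  expect_equal(sort(unlist(folds)), 1:103)
  sizes <- lengths(folds)
  expect_lte(max(sizes) - min(sizes), 1)
  pos_per_fold <- vapply(folds, function(f) sum(ds$labels[f] == 1), 0L)
  expect_lte(max(pos_per_fold) - min(pos_per_fold), 1)
  expect_identical(folds, kfold_partition(ds, 5, seed = 2))
  expect_error(kfold_partition(ds, 200, seed = 1), "exceeds")
})

test_that("dataset scaling confines bounds to the training side", {
  ds <- make_planted_dataset(60, n_features = 4, positive_fraction = 0.5,
                             n_flank = 2, seed = 11)
  raw <- og_dataset(ds$x_raw, ds$labels, ds$feature_names, ds$meta,
                    n_flank = ds$n_flank)
  parts <- split_train_test(raw, 0.25, seed = 1)
  bounds <- fit_dataset_scaler(parts$train)
  tr <- apply_dataset_scaler(parts$train, bounds)
  te <- apply_dataset_scaler(parts$test, bounds)
  env <- !startsWith(tr$feature_names, "aa_")
  expect_true(all(tr$x[, , env] >= 0 & tr$x[, , env] <= 1))
  expect_true(all(te$x[, , env] >= 0 & te$x[, , env] <= 1))
  # scaling leaves the one-hot block untouched
  expect_identical(tr$x[, , !env], parts$train$x[, , !env])
})
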