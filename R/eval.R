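#' Confusion counts
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return One-row tibble `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) abort("length mismatch")
  stopifnot(all(truth %in% c(0, 1)), all(predicted %in% c(0, 1)))
  tibble::tibble(
    TP = sum(truth == 1 & predicted == 1),
    FP = sum(truth == 0 & predicted == 1),
    TN = sum(truth == 0 & predicted == 0),
    FN = sum(truth == 1 & predicted == 0))
}

#' Classification metrics
#'
#' Accuracy, precision, recall and F1 (harmonic mean of precision and
#' recall) from confusion counts, as fractions in `[0, 1]`. Degenerate
#' 0/0 cases (no predicted positives, no true positives) evaluate to 0.
#'
#' @param counts One-row tibble/list with `TP`, `FP`, `TN`, `FN`.
#' @return One-row tibble `accuracy`, `precision`, `recall`, `f1`.
#' @export
metrics <- function(counts) {
  tot <- counts$TP + counts$FP + counts$TN + counts$FN
  if (tot == 0) abort("no samples")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  p <- safe_div(counts$TP, counts$TP + counts$FP)
  r <- safe_div(counts$TP, counts$TP + counts$FN)
  tibble::tibble(
    accuracy = (counts$TP + counts$TN) / tot,
    precision = p, recall = r,
    f1 = safe_div(2 * p * r, p + r))
}

#' Evaluate a fitted model on a test set
#'
#' @param fit An `srnn_fit`.
#' @param test Test [og_dataset()] (left untouched by oversampling).
#' @param threshold Decision threshold (default 0.5).
#' @return One-row metrics tibble (see [metrics()]).
#' @export
evaluate_model <- function(fit, test, threshold = 0.5) {
  pred <- classify(predict_proba(fit, test), threshold)
  metrics(confusion_counts(test$labels, pred))
}

#' Weight-based feature importance
#'
#' Ranks input features by the L2 norm of their input weight group (the
#' feature's row of the LSTM input matrix across all four gates): features
#' whose groups were driven to zero by the sparsity penalty rank last,
#' features carrying large weights rank first. Ties break deterministically
#' by feature name.
#'
#' @param model A (trained) `srnn_model`.
#' @return Tibble `feature`, `score`, `rank`, sorted by descending score;
#'   class `feature_ranking`.
#' @export
feature_importance <- function(model) {
  Wx <- model$params$Wx
  score <- sqrt(rowSums(Wx^2))
  feature <- model$feature_names %||% paste0("f", seq_len(nrow(Wx)))
  ord <- order(-score, feature)
  out <- tibble::tibble(feature = feature[ord], score = score[ord],
                        rank = seq_along(ord))
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Select the top fraction of a ranking
#'
#' Keeps the first `ceiling(fraction * n)` features, so e.g. the top 20%
#' of 498 features is 100 features.
#'
#' @param ranking A `feature_ranking` tibble (or any tibble with a
#'   `feature` column in rank order).
#' @param fraction Value in (0, 1].
#' @return Character vector of selected feature names.
#' @export
select_top_fraction <- function(ranking, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(ranking) == 0L) abort("empty ranking")
  head(ranking$feature, ceiling(fraction * nrow(ranking)))
}

#' Restrict a dataset to a feature subset
#'
#' @param dataset An [og_dataset()].
#' @param keep Character vector of feature names to keep (order of the
#'   original schema is preserved).
#' @return `og_dataset` with the reduced feature dimension.
#' @export
dataset_select_features <- function(dataset, keep) {
  keep_ix <- which(dataset$feature_names %in% keep)
  if (length(keep_ix) == 0L) abort("no features left after selection")
  nm <- dataset$feature_names[keep_ix]
  og_dataset(dataset$x[, , keep_ix, drop = FALSE], dataset$labels, nm,
             dataset$meta, n_flank = dataset$n_flank,
             scaled = dataset$scaled,
             scaler = if (!is.null(dataset$scaler))
               dataset$scaler[dataset$scaler$feature %in% nm, , drop = FALSE],
             x_raw = if (!is.null(dataset$x_raw))
               dataset$x_raw[, , keep_ix, drop = FALSE])
}

#' F1 across top-ranked feature fractions
#'
#' Trains a regularized ranking model on a stratified train split, ranks
#' the local-environment features by input-group weight norm, and then for
#' each requested fraction retrains on only the selected top features
#' (the 20-column one-hot block is always kept) and measures test F1. The
#' baseline is an unregularized model on all features. With
#' `retrain = FALSE`, the ranking model is reused and deselected features
#' are masked to zero at prediction time instead.
#'
#' @param dataset Full [og_dataset()].
#' @param spec Regularized [srnn_spec()] used for ranking (and for the
#'   per-fraction retrains).
#' @param fractions Ascending fractions in (0, 1].
#' @param seed Split/training seed.
#' @param retrain Retrain per fraction (default) or mask the input.
#' @param threshold Decision threshold.
#' @return Tibble `fraction`, `n_features`, `f1` with attribute
#'   `baseline_f1` (all features, no regularization); class
#'   `ranking_curve`.
#' @export
f1_vs_fraction_curve <- function(dataset, spec,
                                 fractions = c(0.05, 0.1, 0.2, 0.4, 1),
                                 seed = 1, retrain = TRUE, threshold = 0.5) {
  stopifnot(all(diff(fractions) > 0))
  parts <- split_train_test(dataset, test_fraction = 0.2, seed = seed)
  rank_fit <- fit_site_model(parts$train, spec, seed = seed)
  ranking <- feature_importance(rank_fit)
  env_ranking <- ranking[!startsWith(ranking$feature, "aa_"), , drop = FALSE]
  onehot <- dataset$feature_names[startsWith(dataset$feature_names, "aa_")]
  base_spec <- spec
  base_spec$reg_input <- "none"; base_spec$reg_hidden <- "none"
  base_spec$lambda <- 0
  base_fit <- fit_site_model(parts$train, base_spec, seed = seed)
  baseline_f1 <- evaluate_model(base_fit, parts$test, threshold)$f1
  f1s <- numeric(length(fractions))
  nfeat <- integer(length(fractions))
  for (i in seq_along(fractions)) {
    sel <- select_top_fraction(env_ranking, fractions[i])
    nfeat[i] <- length(sel)
    if (retrain) {
      sub_spec <- spec
      sub_spec$input_dim <- length(onehot) + length(sel)
      tr <- dataset_select_features(parts$train, c(onehot, sel))
      te <- dataset_select_features(parts$test, c(onehot, sel))
      fit <- fit_site_model(tr, sub_spec, seed = seed)
      f1s[i] <- evaluate_model(fit, te, threshold)$f1
    } else {
      te <- parts$test
      if (!isTRUE(te$scaled) && !is.null(rank_fit$scaler)) {
        te <- apply_dataset_scaler(te, rank_fit$scaler)
      }
      drop_ix <- which(!(te$feature_names %in% c(onehot, sel)))
      te$x[, , drop_ix] <- 0
      pred <- classify(predict_proba(rank_fit, te$x), threshold)
      f1s[i] <- metrics(confusion_counts(te$labels, pred))$f1
    }
  }
  out <- tibble::tibble(fraction = fractions, n_features = nfeat, f1 = f1s)
  attr(out, "baseline_f1") <- baseline_f1
  attr(out, "ranking") <- ranking
  class(out) <- c("ranking_curve", class(out))
  out
}

#' Monte-Carlo cross-validation
#'
#' Repeats the whole evaluation protocol: a fresh stratified 80/20
#' train/test split per repeat (seed = `seed + r`), scaler fit and positive
#' oversampling on the training side only, training with early stopping,
#' and thresholded metrics on the untouched test split. Reports per-repeat
#' metrics and their mean and standard deviation.
#'
#' @param dataset Full [og_dataset()].
#' @param spec An [srnn_spec()].
#' @param repeats Number of repeats (default 5).
#' @param seed Base seed.
#' @param test_fraction Test fraction per repeat.
#' @param threshold Decision threshold.
#' @return List with `per_repeat` (tibble, one row per repeat) and
#'   `summary` (tibble `metric`, `mean`, `sd`); class `og_mccv`.
#' @export
monte_carlo_cv <- function(dataset, spec, repeats = 5, seed = 1,
                           test_fraction = 0.2, threshold = 0.5) {
  stopifnot(repeats >= 1)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    parts <- split_train_test(dataset, test_fraction, seed = seed + r)
    fit <- fit_site_model(parts$train, spec, seed = seed + r)
    rows[[r]] <- dplyr::bind_cols(
      tibble::tibble(repeat_id = r),
      evaluate_model(fit, parts$test, threshold))
  }
  per_repeat <- dplyr::bind_rows(rows)
  summary <- per_repeat |>
    tidyr::pivot_longer(-"repeat_id", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (repeats > 1) sd(.data$value) else 0,
                     .groups = "drop")
  structure(list(per_repeat = per_repeat, summary = summary),
            class = "og_mccv")
}

#' @export
print.og_mccv <- function(x, ...) {
  cat(sprintf("<og_mccv> %d repeats\n", nrow(x$per_repeat)))
  print(x$summary)
  invisible(x)
}

#' Choose the regularization strength by k-fold cross-validation
#'
#' For each candidate lambda, trains on k-1 folds (with scaling and
#' oversampling confined to the training side) and measures F1 on the held
#' fold; picks the lambda with the highest mean F1.
#'
#' @param dataset Training [og_dataset()].
#' @param spec Base [srnn_spec()]; its `lambda` is overridden.
#' @param lambdas Candidate values (default logarithmic grid 1e-5..1e-1).
#' @param k Folds (default 5).
#' @param seed Seed for fold assignment and training.
#' @return List `best_lambda` and `results` (tibble `lambda`, `mean_f1`,
#'   `sd_f1`).
#' @export
cv_lambda <- function(dataset, spec, lambdas = 10^seq(-5, -1), k = 5,
                      seed = 1) {
  folds <- kfold_partition(dataset, k, seed = seed)
  res <- lapply(lambdas, function(lam) {
    sp <- spec; sp$lambda <- lam
    f1s <- vapply(seq_len(k), function(f) {
      test_ix <- folds[[f]]
      train <- dataset_subset(dataset, setdiff(seq_len(n_samples(dataset)),
                                               test_ix))
      fit <- fit_site_model(train, sp, seed = seed + f)
      evaluate_model(fit, dataset_subset(dataset, test_ix))$f1
    }, numeric(1))
    tibble::tibble(lambda = lam, mean_f1 = mean(f1s), sd_f1 = sd(f1s))
  })
  results <- dplyr::bind_rows(res)
  list(best_lambda = results$lambda[which.max(results$mean_f1)],
       results = results)
}

#' Signed mean-value ratio between classes
#'
#' Compares a feature's mean in positive vs negative samples as a signed
#' ratio: `xbar_pos / xbar_neg` when the positive mean is at least the
#' negative mean, `-xbar_neg / xbar_pos` otherwise. The magnitude is always
#' >= 1; the sign says which class is enriched. Equality (including both
#' means zero) gives +1; a zero denominator with a nonzero numerator is
#' flagged as a signed infinity.
#'
#' @param xbar_pos,xbar_neg Finite class means.
#' @return List with `ratio` (numeric, possibly `Inf`/`-Inf`) and `flag`
#'   (`"ok"`, `"pos_inf"` or `"neg_inf"`).
#' @export
mean_ratio <- function(xbar_pos, xbar_neg) {
  stopifnot(is.finite(xbar_pos), is.finite(xbar_neg))
  if (xbar_pos == xbar_neg) return(list(ratio = 1, flag = "ok"))
  if (xbar_pos > xbar_neg) {
    if (xbar_neg == 0) return(list(ratio = Inf, flag = "pos_inf"))
    list(ratio = xbar_pos / xbar_neg, flag = "ok")
  } else {
    if (xbar_pos == 0) return(list(ratio = -Inf, flag = "neg_inf"))
    list(ratio = -xbar_neg / xbar_pos, flag = "ok")
  }
}

#' Subsite mean-ratio profile of a feature
#'
#' For every window position `-N ... +N`, computes the signed mean ratio
#' of a feature's (unscaled) values between positive and negative samples.
#' Ratios use the raw feature values: when the dataset has been scaled the
#' retained `x_raw` array is used.
#'
#' @param dataset An [og_dataset()].
#' @param feature Feature name (must exist in the dataset schema).
#' @return Tibble `position`, `ratio`, `flag`; class `ratio_profile` with
#'   attribute `feature`.
#' @export
ratio_profile <- function(dataset, feature) {
  if (!feature %in% dataset$feature_names) {
    abort(sprintf("unknown feature '%s'", feature))
  }
  x <- dataset$x_raw %||% dataset$x
  fi <- match(feature, dataset$feature_names)
  pos <- dataset$labels == 1
  tt <- dim(x)[2]
  positions <- seq_len(tt) - dataset$n_flank - 1L
  rows <- lapply(seq_len(tt), function(t) {
    v <- x[, t, fi]
    r <- mean_ratio(mean(v[pos]), mean(v[!pos]))
    tibble::tibble(position = positions[t], ratio = r$ratio, flag = r$flag)
  })
  out <- dplyr::bind_rows(rows)
  n_inf <- sum(out$flag != "ok")
  if (n_inf > 0) {
    warn(sprintf("%d position(s) with a zero-denominator ratio (flagged)",
                 n_inf))
  }
  attr(out, "feature") <- feature
  class(out) <- c("ratio_profile", class(out))
  out
}
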