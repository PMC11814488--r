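#' Window dataset container
#'
#' Holds `n` candidate-site samples as a 3D feature array
#' (`n` samples x `2N+1` window positions x `m` per-position features),
#' binary labels, the shared feature-name schema, and per-sample metadata.
#' The first 20 features are the one-hot block (`aa_*`), the remainder the
#' local-environment block; regularization groups and feature selection use
#' this split.
#'
#' @param x Numeric array `n x (2N+1) x m`.
#' @param labels Integer/numeric vector of 0/1 labels, length `n`.
#' @param feature_names Character vector of length `m`.
#' @param meta Tibble with one row per sample (protein id, site, window...).
#' @param n_flank Window half-width N.
#' @param scaled Whether the environment block has been min-max scaled.
#' @param scaler Scaler bounds used (tibble `feature`, `min`, `max`) or NULL.
#' @param x_raw Optional unscaled copy of `x` kept for statistics that must
#'   operate on raw feature values (e.g. mean-ratio profiles).
#' @return An `og_dataset`.
#' @export
og_dataset <- function(x, labels, feature_names, meta = NULL,
                       n_flank = (dim(x)[2] - 1) / 2,
                       scaled = FALSE, scaler = NULL, x_raw = NULL) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == length(labels),
            dim(x)[3] == length(feature_names),
            all(labels %in% c(0, 1)))
  dimnames(x)[[3]] <- feature_names
  if (is.null(meta)) meta <- tibble::tibble(.rows = dim(x)[1])
  structure(list(x = x, labels = as.integer(labels),
                 feature_names = feature_names, meta = meta,
                 n_flank = n_flank, scaled = scaled, scaler = scaler,
                 x_raw = x_raw),
            class = "og_dataset")
}

#' @export
print.og_dataset <- function(x, ...) {
  cat(sprintf(
    "<og_dataset> %d samples (%d pos / %d neg), window %d, %d features%s\n",
    n_samples(x), sum(x$labels == 1), sum(x$labels == 0),
    dim(x$x)[2], length(x$feature_names),
    if (isTRUE(x$scaled)) ", scaled" else ""))
  invisible(x)
}

#' @rdname og_dataset
#' @param dataset An `og_dataset`.
#' @export
n_samples <- function(dataset) dim(dataset$x)[1]

#' @rdname og_dataset
#' @param idx Integer vector of sample indices (repeats allowed).
#' @export
dataset_subset <- function(dataset, idx) {
  stopifnot(all(idx >= 1), all(idx <= n_samples(dataset)))
  og_dataset(dataset$x[idx, , , drop = FALSE], dataset$labels[idx],
             dataset$feature_names, dataset$meta[idx, , drop = FALSE],
             n_flank = dataset$n_flank, scaled = dataset$scaled,
             scaler = dataset$scaler,
             x_raw = if (!is.null(dataset$x_raw))
               dataset$x_raw[idx, , , drop = FALSE])
}

# names of the environment (non one-hot) features
env_feature_names <- function(dataset) {
  dataset$feature_names[!startsWith(dataset$feature_names, "aa_")]
}

#' Min-max feature scaling
#'
#' `fit_scaler()` learns per-feature (min, max) bounds from a training
#' feature table; `apply_scaler()` maps values to `(x - min) / (max - min)`,
#' clipping out-of-range values to `[0, 1]` so unseen data keeps the 0-1
#' contract. Constant features (max == min) map to 0.
#'
#' @param table Data frame or matrix, rows = observations, numeric columns.
#' @return `fit_scaler()`: tibble `feature`, `min`, `max`.
#' @export
fit_scaler <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) == 0L) abort("cannot fit a scaler on an empty table")
  tibble::tibble(feature = colnames(m),
                 min = apply(m, 2, min), max = apply(m, 2, max))
}

#' @rdname fit_scaler
#' @param bounds Result of `fit_scaler()`.
#' @return `apply_scaler()`: object of the same shape with values in `[0, 1]`.
#' @export
apply_scaler <- function(table, bounds) {
  m <- as.matrix(table)
  if (!identical(colnames(m), bounds$feature)) {
    bounds <- bounds[match(colnames(m), bounds$feature), , drop = FALSE]
    if (anyNA(bounds$feature)) abort("scaler bounds missing some features")
  }
  rng <- bounds$max - bounds$min
  rng[rng == 0] <- 1  # constant feature -> (x - min)/1 = 0
  out <- sweep(sweep(m, 2, bounds$min, "-"), 2, rng, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Scale a dataset's environment block
#'
#' Fits min-max bounds on the environment features of a *training* dataset
#' (pooled over all window positions) and applies them to any dataset with
#' the same schema. The one-hot block is already binary and is left
#' untouched; the unscaled array is retained in `x_raw`.
#'
#' @param dataset Dataset to scale.
#' @param bounds Bounds from `fit_dataset_scaler()`.
#' @return `og_dataset` with `scaled = TRUE`.
#' @export
fit_dataset_scaler <- function(dataset) {
  env <- env_feature_names(dataset)
  flat <- matrix(dataset$x[, , env], ncol = length(env),
                 dimnames = list(NULL, env))
  fit_scaler(flat)
}

#' @rdname fit_dataset_scaler
#' @export
apply_dataset_scaler <- function(dataset, bounds) {
  if (isTRUE(dataset$scaled)) return(dataset)
  env <- env_feature_names(dataset)
  x <- dataset$x
  n <- dim(x)[1]; tt <- dim(x)[2]
  flat <- matrix(x[, , env], ncol = length(env),
                 dimnames = list(NULL, env))
  x[, , env] <- array(apply_scaler(flat, bounds), dim = c(n, tt, length(env)))
  og_dataset(x, dataset$labels, dataset$feature_names, dataset$meta,
             n_flank = dataset$n_flank, scaled = TRUE, scaler = bounds,
             x_raw = dataset$x_raw %||% dataset$x)
}

#' Assemble a window dataset from sequences, site labels and features
#'
#' Builds, for each labeled candidate site, its `+/-N` window, the one-hot
#' block at every window position, and the local-environment block looked
#' up from a per-residue feature table. Pad positions (window overhanging a
#' terminus) get all-zero rows; residues without a feature row also encode
#' as zeros (with a warning).
#'
#' @param sites Tibble with columns `protein_id`, `site` (1-based), `label`
#'   (0/1).
#' @param sequences Named character vector, protein id -> sequence (see
#'   [read_sequences()]).
#' @param env_features Tibble as returned by [featurize_sites()] for every
#'   residue that can appear in a window (columns `structure_id`, `site`,
#'   features). `NULL` for a sequence-only (one-hot) dataset.
#' @param n_flank Window half-width N (default 10).
#' @return An unscaled [og_dataset()].
#' @export
assemble_samples <- function(sites, sequences, env_features = NULL,
                             n_flank = 10) {
  stopifnot(all(c("protein_id", "site", "label") %in% names(sites)))
  missing_prot <- setdiff(unique(sites$protein_id), names(sequences))
  if (length(missing_prot) > 0) {
    abort(paste("no sequence for protein(s):",
                paste(missing_prot, collapse = ",")))
  }
  env_names <- character(0)
  env_lookup <- NULL
  if (!is.null(env_features)) {
    env_names <- setdiff(names(env_features), c("structure_id", "site"))
    env_lookup <- as.matrix(env_features[, env_names, drop = FALSE])
    rownames(env_lookup) <- paste(env_features$structure_id,
                                  env_features$site, sep = "|")
  }
  tt <- 2L * n_flank + 1L
  feature_names <- c(paste0("aa_", AA_ALPHABET), env_names)
  m <- length(feature_names)
  n <- nrow(sites)
  x <- array(0, dim = c(n, tt, m), dimnames = list(NULL, NULL, feature_names))
  windows <- character(n)
  n_unmatched <- 0L
  for (i in seq_len(n)) {
    seqc <- sequences[[sites$protein_id[i]]]
    w <- build_window(seqc, sites$site[i], n_flank)
    windows[i] <- w
    x[i, , seq_len(20)] <- one_hot_encode(w)
    if (!is.null(env_lookup)) {
      pos <- (sites$site[i] - n_flank):(sites$site[i] + n_flank)
      keys <- paste(sites$protein_id[i], pos, sep = "|")
      inseq <- pos >= 1 & pos <= nchar(seqc)
      hit <- match(keys, rownames(env_lookup))
      use <- inseq & !is.na(hit)
      n_unmatched <- n_unmatched + sum(inseq & is.na(hit))
      if (any(use)) {
        x[i, which(use), 20L + seq_along(env_names)] <-
          env_lookup[hit[use], , drop = FALSE]
      }
    }
  }
  if (n_unmatched > 0) {
    warn(sprintf("%d in-sequence window positions had no feature row (encoded as zeros)",
                 n_unmatched))
  }
  og_dataset(x, sites$label, feature_names,
             meta = tibble::tibble(protein_id = sites$protein_id,
                                   site = sites$site, window = windows),
             n_flank = n_flank)
}

# stratified index draw: for each label class, assign round(frac * n_c)
# samples to the second part (at least 1 when the class has >= 2 samples)
stratified_holdout <- function(labels, fraction, seed) {
  if (any(tabulate(labels + 1L, 2L) == 0L)) {
    abort("both classes must be present for a stratified split")
  }
  idx_out <- integer(0)
  withr::with_seed(seed, {
    for (cl in c(0L, 1L)) {
      members <- which(labels == cl)
      k <- round(fraction * length(members))
      if (length(members) >= 2L) k <- max(1L, min(length(members) - 1L, k))
      idx_out <- c(idx_out, sample(members, k))
    }
  })
  sort(idx_out)
}

#' Stratified train/test split
#'
#' Disjoint, exhaustive, stratified by label and reproducible for a given
#' seed. Stratification matters here: at a ~1:26 class imbalance an
#' unstratified 20% test draw can easily lose every positive.
#'
#' @param dataset An [og_dataset()].
#' @param test_fraction Fraction held out for testing (default 0.2).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(dataset, test_fraction = 0.2, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  test_idx <- stratified_holdout(dataset$labels, test_fraction, seed)
  list(train = dataset_subset(dataset, setdiff(seq_len(n_samples(dataset)),
                                               test_idx)),
       test = dataset_subset(dataset, test_idx))
}

#' Balance a training set by replicating positives
#'
#' Replicates positive samples until their count matches the negatives:
#' every positive appears `floor(n_neg / n_pos)` times, and the remainder
#' is drawn from the positives without replacement. Negatives are
#' untouched. Apply only to training data, never to validation/test sets.
#'
#' @param dataset Training [og_dataset()].
#' @param seed Seed for the remainder draw.
#' @return Balanced `og_dataset`.
#' @export
oversample_positives <- function(dataset, seed = 1) {
  pos <- which(dataset$labels == 1)
  neg <- which(dataset$labels == 0)
  if (length(pos) == 0L) abort("no positive samples to replicate")
  if (length(neg) == 0L) abort("no negative samples")
  if (length(pos) >= length(neg)) return(dataset)
  whole <- length(neg) %/% length(pos)
  rem <- length(neg) - whole * length(pos)
  extra <- if (rem > 0) withr::with_seed(seed, sample(pos, rem)) else integer(0)
  dataset_subset(dataset, c(rep(pos, whole), extra, neg))
}

#' Stratified k-fold partition
#'
#' @param dataset An [og_dataset()].
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed.
#' @return List of `k` disjoint index vectors whose union is all samples;
#'   per-class fold sizes differ by at most 1.
#' @export
kfold_partition <- function(dataset, k, seed = 1) {
  n <- n_samples(dataset)
  stopifnot(k >= 2)
  if (k > n) abort("k exceeds the number of samples")
  folds <- vector("list", k)
  counts <- numeric(k)  # running fold sizes, to keep totals within 1
  withr::with_seed(seed, {
    for (cl in c(0L, 1L)) {
      members <- sample(which(dataset$labels == cl))
      sizes <- rep(length(members) %/% k, k)
      rem <- length(members) %% k
      if (rem > 0) {
        ord <- order(counts, seq_len(k))
        sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
      }
      stop_at <- cumsum(sizes)
      start_at <- c(1L, head(stop_at, -1) + 1L)
      for (f in seq_len(k)) {
        if (sizes[f] > 0) {
          folds[[f]] <- c(folds[[f]], members[start_at[f]:stop_at[f]])
        }
      }
      counts <- counts + sizes
    }
  })
  lapply(folds, sort)
}
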