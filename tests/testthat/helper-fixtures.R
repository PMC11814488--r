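# shared fixtures and independent oracles for the test suite

# brute-force neighborhood oracle: all-pairs heavy-atom distance scan
brute_residues_within <- function(structure, center, cutoff) {
  a <- structure$atoms[!structure$atoms$is_hydrogen, , drop = FALSE]
  ca <- a[a$residue == center, , drop = FALSE]
  hits <- vapply(structure$residues$residue, function(r) {
    b <- a[a$residue == r, , drop = FALSE]
    if (nrow(b) == 0) return(FALSE)
    dmin <- Inf
    for (i in seq_len(nrow(ca))) {
      for (j in seq_len(nrow(b))) {
        d <- sqrt((ca$x[i] - b$x[j])^2 + (ca$y[i] - b$y[j])^2 +
                    (ca$z[i] - b$z[j])^2)
        dmin <- min(dmin, d)
      }
    }
    dmin <= cutoff
  }, logical(1))
  sort(unique(c(center, structure$residues$residue[hits])))
}

# random toy structure of up to `max_res` residues
random_toy <- function(seed, max_res = 50) {
  withr::with_seed(seed, {
    n <- sample(3:max_res, 1)
    seqc <- paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
    geom <- sample(c("extended", "helix"), 1)
    make_toy_structure(seqc, geom)
  })
}

# small but non-trivially separable dataset: the positive class carries a
# deterministic indicator on one feature at the window center
separable_dataset <- function(n = 300, seed = 1) {
  n_flank <- 2
  tt <- 2 * n_flank + 1
  feature_names <- c(paste0("aa_", AA_ALPHABET), "envsig", "envnoise")
  withr::with_seed(seed, {
    labels <- rep(c(0L, 1L), length.out = n)
    x <- array(0, dim = c(n, tt, length(feature_names)),
               dimnames = list(NULL, NULL, feature_names))
    for (i in seq_len(n)) {
      w <- sample(AA_ALPHABET, tt, replace = TRUE)
      w[n_flank + 1] <- sample(c("S", "T"), 1)
      x[i, , 1:20] <- one_hot_encode(paste(w, collapse = ""))
    }
    x[, , "envsig"] <- 0.1 * matrix(runif(n * tt), n, tt)
    x[labels == 1, n_flank + 1, "envsig"] <- 1
    x[, , "envnoise"] <- matrix(runif(n * tt), n, tt)
  })
  og_dataset(x, labels, feature_names, n_flank = n_flank, scaled = TRUE)
}

# spec for quick training runs on separable_dataset()
quick_spec <- function(..., seed = 1) {
  args <- modifyList(
    list(input_dim = 22, n_flank = 2, hidden_size = 6, dense_sizes = 4,
         max_epochs = 50, patience = 10, batch_size = 64, seed = seed),
    list(...))
  do.call(srnn_spec, args)
}
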