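#' Toy protein structures with exactly known geometry
#'
#' Builds small polypeptide structures whose neighborhood and SASA
#' arithmetic can be checked by hand: in `extended` mode the C-alpha atoms
#' lie on a line at `ca_spacing` Angstrom intervals, in `helix` mode on an
#' ideal alpha-helix (radius 2.3 A, rise 1.5 A, 100 degrees per residue).
#' Side chains are single pseudo-atoms (a CB carbon offset 1.5 A
#' perpendicular to the chain axis) for every residue except glycine;
#' `custom` mode takes atom coordinates verbatim.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet.
#' @param geometry `"extended"`, `"helix"` or `"custom"`.
#' @param ca_spacing C-alpha spacing in Angstrom for extended mode
#'   (default 3.8).
#' @param coords For custom mode: tibble with `residue`, `name`, `element`,
#'   `x`, `y`, `z`.
#' @param id Structure identifier.
#' @return A [protein_structure()].
#' @export
make_toy_structure <- function(sequence,
                               geometry = c("extended", "helix", "custom"),
                               ca_spacing = 3.8, coords = NULL,
                               id = "toy") {
  geometry <- match.arg(geometry)
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) == 0L) abort("empty sequence")
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("unknown residue(s): %s", paste(unique(bad), collapse = ",")))
  }
  if (geometry == "custom") {
    if (is.null(coords)) abort("custom geometry needs a coords table")
    atoms <- tibble::as_tibble(coords)
    atoms$serial <- seq_len(nrow(atoms))
    atoms$aa_code <- chars[atoms$residue]
    return(protein_structure(id, atoms, source_format = "memory"))
  }
  stopifnot(ca_spacing > 0)
  n <- length(chars)
  if (geometry == "extended") {
    ca <- cbind((seq_len(n) - 1) * ca_spacing, 0, 0)
    cb_off <- c(0, 1.5, 0)
  } else {
    ang <- (seq_len(n) - 1) * 100 * pi / 180
    ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), (seq_len(n) - 1) * 1.5)
    cb_off <- NULL  # radial offset, computed per residue below
  }
  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    serial <- serial + 1L
    rows[[length(rows) + 1]] <- tibble::tibble(
      serial = serial, name = "CA", element = "C",
      x = ca[i, 1], y = ca[i, 2], z = ca[i, 3], residue = i,
      aa_code = chars[i])
    if (chars[i] != "G") {
      off <- if (geometry == "extended") cb_off else {
        u <- c(ca[i, 1], ca[i, 2], 0)
        1.5 * u / sqrt(sum(u^2))
      }
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- tibble::tibble(
        serial = serial, name = "CB", element = "C",
        x = ca[i, 1] + off[1], y = ca[i, 2] + off[2], z = ca[i, 3] + off[3],
        residue = i, aa_code = chars[i])
    }
  }
  protein_structure(id, dplyr::bind_rows(rows), source_format = "memory")
}

#' Labeled window datasets with planted feature-label signal
#'
#' Generates a desk-scale dataset with known ground truth. Window strings
#' are random sequences with an S/T center; the environment block is drawn
#' from a folded normal `|N(0, noise_sd^2)|` (mirroring the non-negativity
#' of count/SASA features). In positive samples the informative features
#' are shifted upward by `effect_size * noise_sd` at the planted window
#' position(s). The environment block is then min-max scaled to `[0, 1]`
#' (the raw values are retained in `x_raw` for ratio statistics).
#'
#' @param n_samples Total samples.
#' @param n_features Width of the environment block.
#' @param informative Integer indices (into the environment block) of the
#'   features carrying signal.
#' @param effect_size Mean shift in units of `noise_sd`.
#' @param positive_fraction Fraction of positive labels (count is rounded).
#' @param n_flank Window half-width N.
#' @param label_position `"all"` or a subsite position in `-N ... +N` at
#'   which the shift is planted.
#' @param noise_sd Feature noise scale.
#' @param seed RNG seed; same seed, same dataset, bit for bit.
#' @return An [og_dataset()] (scaled) with attribute `planted` naming the
#'   informative features.
#' @export
make_planted_dataset <- function(n_samples, n_features = 60,
                                 informative = integer(0), effect_size = 2,
                                 positive_fraction = 0.5, n_flank = 10,
                                 label_position = "all", noise_sd = 1,
                                 seed = 1) {
  stopifnot(n_samples >= 2, n_features >= 1,
            all(informative >= 1), all(informative <= n_features),
            positive_fraction > 0, positive_fraction < 1, noise_sd > 0)
  tt <- 2L * n_flank + 1L
  if (identical(label_position, "all")) {
    planted_t <- seq_len(tt)
  } else {
    if (abs(label_position) > n_flank) {
      abort(sprintf("label_position %d outside the window +/-%d",
                    label_position, n_flank))
    }
    planted_t <- label_position + n_flank + 1L
  }
  n_pos <- max(1L, round(n_samples * positive_fraction))
  env_names <- sprintf("env%02d", seq_len(n_features))
  feature_names <- c(paste0("aa_", AA_ALPHABET), env_names)
  withr::with_seed(seed, {
    labels <- c(rep(1L, n_pos), rep(0L, n_samples - n_pos))
    labels <- sample(labels)
    windows <- vapply(seq_len(n_samples), function(i) {
      w <- sample(AA_ALPHABET, tt, replace = TRUE)
      w[n_flank + 1L] <- sample(c("S", "T"), 1)
      paste(w, collapse = "")
    }, "")
    env_raw <- array(abs(rnorm(n_samples * tt * n_features, 0, noise_sd)),
                     dim = c(n_samples, tt, n_features))
  })
  pos_ix <- which(labels == 1L)
  env_raw[pos_ix, planted_t, informative] <-
    env_raw[pos_ix, planted_t, informative] + effect_size * noise_sd
  x <- array(0, dim = c(n_samples, tt, 20L + n_features),
             dimnames = list(NULL, NULL, feature_names))
  for (i in seq_len(n_samples)) {
    x[i, , seq_len(20)] <- one_hot_encode(windows[i])
  }
  x_raw <- x
  x_raw[, , 20L + seq_len(n_features)] <- env_raw
  # global min-max scaling of the environment block
  flat <- matrix(env_raw, ncol = n_features, dimnames = list(NULL, env_names))
  bounds <- fit_scaler(flat)
  x[, , 20L + seq_len(n_features)] <-
    array(apply_scaler(flat, bounds), dim = dim(env_raw))
  ds <- og_dataset(
    x, labels, feature_names,
    meta = tibble::tibble(protein_id = "synthetic",
                          site = seq_len(n_samples), window = windows),
    n_flank = n_flank, scaled = TRUE, scaler = bounds, x_raw = x_raw)
  attr(ds, "planted") <- env_names[sort(unique(informative))]
  ds
}

#' Fixed imbalanced benchmark dataset
#'
#' The acceptance-scale study condition: 2700 candidate sites at the ~1:26
#' positive:negative imbalance of real O-GlcNAcome data (100 positives),
#' windows of half-width 10, an environment block of 60 features of which
#' 5 (env07, env19, env31, env43, env55) carry a 2-sigma planted shift at
#' every window position.
#'
#' @param seed RNG seed.
#' @return An [og_dataset()] with attribute `planted`.
#' @export
make_imbalanced_benchmark <- function(seed = 1) {
  make_planted_dataset(
    n_samples = 2700, n_features = 60,
    informative = c(7L, 19L, 31L, 43L, 55L),
    effect_size = 2, positive_fraction = 100 / 2700,
    n_flank = 10, label_position = "all", noise_sd = 1, seed = seed)
}

#' Write a set of desk-scale fixtures to a directory
#'
#' Creates toy structure files (PDB and mmCIF), a FASTA of their sequences,
#' a 1-based site-label table, and a small planted dataset archive, so the
#' whole pipeline can be exercised from files.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed for the planted dataset.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- c(toy1 = "MASTKVLDES", toy2 = "GGSTPQRWYV")
  for (nm in names(seqs)) {
    st <- make_toy_structure(seqs[[nm]], "extended", id = nm)
    write_structure_pdb(st, file.path(dir, paste0(nm, ".pdb")))
    write_structure_cif(st, file.path(dir, paste0(nm, ".cif")))
  }
  writeLines(unlist(lapply(names(seqs), function(nm)
    c(paste0(">", nm), seqs[[nm]]))), file.path(dir, "sequences.fasta"))
  sites <- dplyr::bind_rows(lapply(names(seqs), function(nm) {
    pos <- extract_candidate_sites(seqs[[nm]])
    tibble::tibble(protein_id = nm, site = pos,
                   label = as.integer(seq_along(pos) %% 2L))
  }))
  utils::write.table(sites, file.path(dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ds <- make_planted_dataset(n_samples = 200, n_features = 12,
                             informative = c(2L, 5L), effect_size = 2,
                             positive_fraction = 0.25, n_flank = 5,
                             seed = seed)
  saveRDS(ds, file.path(dir, "planted_dataset.rds"))
  invisible(dir)
}
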