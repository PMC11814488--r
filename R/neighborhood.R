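#' Residues within a radial cutoff of a center residue
#'
#' A residue j is a neighbor of the center residue at cutoff r when the
#' minimum Euclidean distance over atom pairs (one atom from each residue)
#' is <= r. Heavy atoms are used by default, which captures side-chain
#' reach; `method = "calpha"` restricts the distance to the C-alpha atoms.
#' The center itself is always included (its self-distance is 0), so a
#' cutoff of 0 returns exactly the center.
#'
#' @param structure A [protein_structure()].
#' @param center 1-based residue position.
#' @param cutoff Radius in Angstrom (>= 0).
#' @param method `"heavy"` (minimum heavy-atom distance, default) or
#'   `"calpha"`.
#' @param include_hydrogens Also use hydrogen atoms for `method = "heavy"`.
#' @return Sorted integer vector of residue positions (always contains
#'   `center`).
#' @export
residues_within <- function(structure, center, cutoff,
                            method = c("heavy", "calpha"),
                            include_hydrogens = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(structure, "protein_structure"), cutoff >= 0)
  if (!center %in% structure$residues$residue) {
    abort(sprintf("invalid center residue position %s", center))
  }
  a <- structure$atoms
  if (method == "calpha") {
    a <- a[a$name == "CA", , drop = FALSE]
  } else if (!include_hydrogens) {
    a <- a[!a$is_hydrogen, , drop = FALSE]
  }
  ca <- a[a$residue == center, , drop = FALSE]
  if (nrow(ca) == 0L) return(center)
  xyz <- cbind(a$x, a$y, a$z)
  # min over center atoms of squared distance to every atom
  mind2 <- rep(Inf, nrow(a))
  for (k in seq_len(nrow(ca))) {
    d2 <- (xyz[, 1] - ca$x[k])^2 + (xyz[, 2] - ca$y[k])^2 +
      (xyz[, 3] - ca$z[k])^2
    mind2 <- pmin(mind2, d2)
  }
  hit <- unique(a$residue[mind2 <= cutoff^2])
  sort(unique(c(center, hit)))
}

# feature-name schema for a class table and radius ladder; radius 0 yields
# self features (class one-hot of the center plus its own SASA), each
# positive radius a count and a total-SASA feature per class
local_env_feature_names <- function(table, radii) {
  cls <- names(table$classes)
  nm <- character(0)
  if (0 %in% radii) nm <- c(paste0("self_", cls), "self_sasa")
  for (r in sort(radii[radii > 0])) {
    nm <- c(nm, paste0("count_", cls, "_r", r), paste0("sasa_", cls, "_r", r))
  }
  nm
}

#' Local-environment feature vector of one residue
#'
#' For each positive cutoff radius r and each physicochemical class c, the
#' vector holds the number of neighboring residues of class c within r of
#' the center and their total solvent-accessible surface area. Radius 0
#' describes the center alone: its class memberships (0/1) and its own
#' SASA. Counts are non-decreasing in the radius because neighborhoods are
#' nested.
#'
#' @param structure A [protein_structure()].
#' @param center 1-based residue position.
#' @param radii Ascending cutoff ladder in Angstrom; may start at 0.
#'   Default `c(0, 5, 10, 15, 20, 25)`.
#' @param table A [class_table()].
#' @param res_sasa Result of [residue_sasa()]; computed on the fly when
#'   `NULL`.
#' @param ... Passed to [residues_within()] (distance method etc.).
#' @return Named numeric vector over the `local_env_feature_names()` schema.
#' @export
local_environment_vector <- function(structure, center,
                                     radii = c(0, 5, 10, 15, 20, 25),
                                     table = default_class_table(),
                                     res_sasa = NULL, ...) {
  stopifnot(all(diff(radii) > 0), all(radii >= 0))
  if (is.null(res_sasa)) {
    res_sasa <- residue_sasa(structure, compute_sasa(structure))
  }
  if (!center %in% structure$residues$residue) {
    abort(sprintf("invalid center residue position %s", center))
  }
  memb <- class_membership_matrix(table)          # codes x classes
  cls <- names(table$classes)
  sasa_by_res <- setNames(res_sasa$sasa, res_sasa$residue)
  aa_by_res <- setNames(structure$residues$aa_code,
                        structure$residues$residue)
  out <- setNames(numeric(0), character(0))
  if (0 %in% radii) {
    self <- memb[aa_by_res[[as.character(center)]], ]
    out <- c(setNames(as.numeric(self), paste0("self_", cls)),
             self_sasa = unname(sasa_by_res[as.character(center)]))
  }
  for (r in sort(radii[radii > 0])) {
    nb <- residues_within(structure, center, r, ...)
    m <- memb[aa_by_res[as.character(nb)], , drop = FALSE]
    counts <- colSums(m)
    tsasa <- colSums(m * sasa_by_res[as.character(nb)])
    out <- c(out, setNames(counts, paste0("count_", cls, "_r", r)),
             setNames(tsasa, paste0("sasa_", cls, "_r", r)))
  }
  out
}

#' Featurize candidate sites of a structure
#'
#' Computes the local-environment vector for each requested residue
#' position and returns them as one tidy row per site. SASA is computed
#' once per structure. Column names and order are identical across
#' structures for a fixed class table and radius ladder, so tables from
#' several structures can be row-bound directly.
#'
#' @param structure A [protein_structure()].
#' @param sites Integer vector of 1-based residue positions.
#' @param radii,table,... See [local_environment_vector()].
#' @param probe_radius,n_sphere_points,include_hydrogens SASA settings, see
#'   [compute_sasa()].
#' @return Tibble: `structure_id`, `site` (1-based), then one column per
#'   local-environment feature. Zero sites yield a zero-row tibble with the
#'   full header.
#' @export
featurize_sites <- function(structure, sites,
                            radii = c(0, 5, 10, 15, 20, 25),
                            table = default_class_table(),
                            probe_radius = 1.4, n_sphere_points = 960,
                            include_hydrogens = FALSE, ...) {
  bad <- setdiff(sites, structure$residues$residue)
  if (length(bad) > 0) {
    abort(sprintf("site(s) out of range for %s: %s", structure$id,
                  paste(bad, collapse = ",")))
  }
  feat_names <- local_env_feature_names(table, radii)
  if (length(sites) == 0L) {
    empty <- tibble::as_tibble(setNames(
      lapply(feat_names, function(x) numeric(0)), feat_names))
    return(dplyr::bind_cols(
      tibble::tibble(structure_id = character(0), site = integer(0)), empty))
  }
  rs <- residue_sasa(structure, compute_sasa(
    structure, probe_radius = probe_radius,
    n_sphere_points = n_sphere_points,
    include_hydrogens = include_hydrogens))
  rows <- lapply(sites, function(s) {
    local_environment_vector(structure, s, radii = radii, table = table,
                             res_sasa = rs, ...)
  })
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(
    tibble::tibble(structure_id = structure$id, site = as.integer(sites)),
    tibble::as_tibble(mat))
}
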