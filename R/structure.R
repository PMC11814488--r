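#' Bundled van der Waals radii
#'
#' Bondi-style element radii (Angstrom) used for all solvent-accessibility
#' and contact computations. Shipped with the package (rather than taken
#' from an external source at run time) so that results are bit-reproducible
#' across installations.
#'
#' @return Named numeric vector, element symbol -> radius in Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92)
}

#' Protein structure container
#'
#' A light tabular container for a (possibly multi-chain) protein structure:
#' one row per atom with coordinates, element, van der Waals radius, an
#' optional partial charge, a hydrogen flag, and the 1-based residue position
#' it belongs to. Residue positions are strictly increasing in chain order
#' and the amino-acid sequence is derivable from them.
#'
#' @param id Structure identifier.
#' @param atoms Tibble/data.frame with columns `serial`, `name`, `element`,
#'   `x`, `y`, `z`, `residue`, `aa_code`, and optionally `partial_charge`.
#' @param source_format `"pdb"`, `"cif"` or `"memory"`.
#' @param unknown_element What to do with atoms whose element has no bundled
#'   vdW radius: `"skip"` (drop with a warning, the default) or `"error"`.
#' @return A `protein_structure` object.
#' @export
protein_structure <- function(id, atoms, source_format = "memory",
                              unknown_element = c("skip", "error")) {
  unknown_element <- match.arg(unknown_element)
  atoms <- tibble::as_tibble(atoms)
  needed <- c("serial", "name", "element", "x", "y", "z", "residue", "aa_code")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste("atoms table lacks columns:", paste(missing, collapse = ",")))
  }
  if (!"partial_charge" %in% names(atoms)) atoms$partial_charge <- NA_real_
  atoms$element <- toupper(atoms$element)
  radii <- vdw_radii()
  known <- atoms$element %in% names(radii)
  if (any(!known)) {
    msg <- sprintf("%d atom(s) with unknown element (%s)",
                   sum(!known), paste(unique(atoms$element[!known]), collapse = ","))
    if (unknown_element == "error") abort(msg)
    warn(paste(msg, "- skipped"))
    atoms <- atoms[known, , drop = FALSE]
  }
  if (nrow(atoms) == 0L) abort("structure has no atoms with usable elements")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("non-finite atom coordinates")
  }
  atoms$vdw_radius <- unname(radii[atoms$element])
  atoms$is_hydrogen <- atoms$element == "H"
  # residues must appear in strictly increasing 1-based position order
  res <- unique(atoms$residue)
  if (any(diff(res) <= 0) || res[1] < 1L) {
    abort("residue positions must be strictly increasing and 1-based")
  }
  counts <- table(factor(atoms$residue, levels = res))
  if (any(counts == 0)) abort("residue with zero atoms")
  aa <- vapply(res, function(r) atoms$aa_code[atoms$residue == r][1], "")
  if (!all(aa %in% c(AA_ALPHABET, "X"))) abort("invalid amino-acid code")
  structure(
    list(id = id, atoms = atoms,
         residues = tibble::tibble(residue = as.integer(res), aa_code = aa),
         source_format = source_format),
    class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d residues, %d atoms (%d H) [%s]\n",
              x$id, nrow(x$residues), nrow(x$atoms),
              sum(x$atoms$is_hydrogen), x$source_format))
  cat(" sequence:", structure_sequence(x), "\n")
  invisible(x)
}

#' @rdname protein_structure
#' @param structure A `protein_structure`.
#' @export
structure_sequence <- function(structure) {
  paste(structure$residues$aa_code, collapse = "")
}

#' @rdname protein_structure
#' @export
n_residues <- function(structure) nrow(structure$residues)

# element symbol from a PDB atom name when the element column is absent:
# strip digits/primes, atom names whose first alpha character is H are
# hydrogens (covers 1HB etc.); otherwise first character, preferring
# two-letter matches (CL, BR, SE) against the bundled radius table
infer_element <- function(name) {
  stripped <- toupper(gsub("[^A-Za-z]", "", name))
  vapply(stripped, function(s) {
    if (nchar(s) == 0) return(NA_character_)
    two <- substr(s, 1, 2)
    if (two %in% c("CL", "BR", "SE") ) return(two)
    one <- substr(s, 1, 1)
    one
  }, "", USE.NAMES = FALSE)
}

#' Read a protein structure from PDB or mmCIF
#'
#' Parses a structure file with bio3d and converts it to the package's
#' [protein_structure()] container. Only the first model of a multi-model
#' file is used (a message is emitted). Hydrogens are retained but flagged;
#' downstream SASA/neighborhood computations exclude them by default.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param id Structure identifier; defaults to the file base name.
#' @param charge_column Optional name of a per-atom numeric column of the
#'   parsed file to interpret as partial charges (e.g. `"b"` or `"o"` when a
#'   force-field pipeline wrote charges into the B-factor/occupancy field).
#' @param unknown_element See [protein_structure()].
#' @return A [protein_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           id = NULL, charge_column = NULL,
                           unknown_element = c("skip", "error")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- if (format == "pdb") {
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  } else {
    # bio3d's read.cif warns about its beta status and absent helix/sheet
    # records on every call; neither affects the atom table we consume
    withCallingHandlers(
      bio3d::read.cif(path, verbose = FALSE),
      warning = function(w) {
        if (grepl("beta version|helix/sheet", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  at <- parsed$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0) abort("no atom records parsed")
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- infer_element(at$elety[blank])
  # hydrogens named like 1HB / HB2 get misassigned by first-letter inference
  halike <- blank & grepl("^[0-9]*H", toupper(gsub("'", "", at$elety)))
  elem[halike] <- "H"
  # 1-based residue positions in file order
  res_key <- paste(at$chain, at$resno, at$insert, sep = "|")
  pos <- as.integer(factor(res_key, levels = unique(res_key)))
  aa <- suppressWarnings(bio3d::aa321(at$resid))
  aa[is.na(aa) | !aa %in% AA_ALPHABET] <- "X"
  charge <- if (!is.null(charge_column)) as.numeric(at[[charge_column]]) else NA_real_
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno), name = trimws(at$elety),
    element = toupper(trimws(elem)),
    x = at$x, y = at$y, z = at$z,
    residue = pos, aa_code = aa, partial_charge = charge)
  protein_structure(id = id %||% sub("\\.[^.]*$", "", basename(path)),
                    atoms = atoms, source_format = format,
                    unknown_element = unknown_element)
}

#' Write a structure to a (minimal) PDB or mmCIF file
#'
#' Round-trip writers used mainly for fixtures: the written file re-parses
#' with [read_structure()] to a field-equal structure.
#'
#' @param structure A [protein_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  resid3 <- bio3d::aa123(a$aa_code)
  resid3[a$aa_code == "X"] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, substr(paste0(" ", a$name), 1, 4), resid3, a$residue,
    a$x, a$y, a$z, 1.00, 0.00, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname write_structure_pdb
#' @export
write_structure_cif <- function(structure, path) {
  a <- structure$atoms
  resid3 <- bio3d::aa123(a$aa_code)
  resid3[a$aa_code == "X"] <- "UNK"
  hdr <- c(
    sprintf("data_%s", gsub("[^A-Za-z0-9]", "_", structure$id)),
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf(
    "ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s A %s 1",
    a$serial, a$element, a$name, resid3, a$residue, a$x, a$y, a$z,
    a$residue, resid3, a$name)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
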