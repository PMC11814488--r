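#' Physicochemical class tables
#'
#' A class table maps named physicochemical classes (hydrophobic, aliphatic,
#' charged, size classes, ...) to subsets of the 20 amino acids. It defines
#' the schema of the local-environment features: each class contributes one
#' neighbor-count and one total-SASA feature per radial cutoff. Classes may
#' overlap freely; optionally, sets of class names can be declared as
#' *partition groups*, meaning that together they cover the alphabet exactly
#' once (e.g. small/large). Partition groups give a conservation invariant:
#' their counts sum to the neighborhood size at every radius.
#'
#' @param classes Named list; each element a character vector of one-letter
#'   amino-acid codes (subset of [AA_ALPHABET]).
#' @param partition_groups Optional list of character vectors of class names;
#'   each declared group must partition the 20-letter alphabet exactly.
#' @return An object of class `class_table`.
#' @examples
#' tab <- default_class_table()
#' classify_residue("K", tab)
#' @export
class_table <- function(classes, partition_groups = list()) {
  stopifnot(is.list(classes), length(classes) > 0)
  if (is.null(names(classes)) || any(names(classes) == "")) {
    abort("every class must be named")
  }
  for (nm in names(classes)) {
    bad <- setdiff(classes[[nm]], AA_ALPHABET)
    if (length(bad) > 0) {
      abort(sprintf("class '%s' contains non-standard codes: %s",
                    nm, paste(bad, collapse = ",")))
    }
  }
  for (grp in partition_groups) {
    missing <- setdiff(grp, names(classes))
    if (length(missing) > 0) {
      abort(sprintf("partition group refers to unknown classes: %s",
                    paste(missing, collapse = ",")))
    }
    members <- unlist(classes[grp], use.names = FALSE)
    if (length(members) != 20L || !setequal(members, AA_ALPHABET) ||
        anyDuplicated(members) > 0) {
      abort(sprintf("classes {%s} do not partition the alphabet",
                    paste(grp, collapse = ",")))
    }
  }
  structure(list(classes = classes, partition_groups = partition_groups),
            class = "class_table")
}

#' @rdname class_table
#' @details `default_class_table()` ships the package's reconstruction of a
#'   typical physicochemical inventory (10 overlapping classes covering
#'   hydrophobicity, aromaticity, polarity, charge, size and hydroxyl
#'   content). The small/large pair is declared as a partition group.
#' @export
default_class_table <- function() {
  class_table(
    classes = list(
      aliphatic          = c("A", "V", "L", "I"),
      aromatic           = c("F", "W", "Y", "H"),
      hydrophobic        = c("A", "V", "L", "I", "M", "F", "W", "C"),
      nonpolar           = c("G", "A", "V", "L", "I", "P", "F", "M", "W"),
      polar_uncharged    = c("S", "T", "N", "Q", "C", "Y"),
      positively_charged = c("K", "R", "H"),
      negatively_charged = c("D", "E"),
      small              = c("G", "A", "S", "C", "T", "P", "N", "D", "V"),
      large              = c("F", "W", "Y", "R", "K", "M", "I", "L", "H", "E", "Q"),
      hydroxyl           = c("S", "T", "Y")
    ),
    partition_groups = list(size = c("small", "large"))
  )
}

#' Classify an amino acid
#'
#' Returns every class of `table` that contains `aa_code`. The unknown
#' residue code `"X"` belongs to no class.
#'
#' @param aa_code Single one-letter amino-acid code.
#' @param table A [class_table()].
#' @return Character vector of class names (possibly empty).
#' @export
classify_residue <- function(aa_code, table = default_class_table()) {
  stopifnot(inherits(table, "class_table"),
            is.character(aa_code), length(aa_code) == 1L)
  if (aa_code == "X") return(character(0))
  if (!aa_code %in% AA_ALPHABET) {
    abort(sprintf("unknown amino-acid code '%s'", aa_code))
  }
  names(table$classes)[vapply(table$classes, function(m) aa_code %in% m,
                              logical(1))]
}

# 0/1 membership matrix: 20 alphabet rows (plus X) x classes, in table order
class_membership_matrix <- function(table) {
  codes <- c(AA_ALPHABET, "X")
  m <- vapply(table$classes, function(members) as.numeric(codes %in% members),
              numeric(length(codes)))
  rownames(m) <- codes
  m
}

#' @export
print.class_table <- function(x, ...) {
  cat(sprintf("<class_table> %d classes\n", length(x$classes)))
  for (nm in names(x$classes)) {
    cat(sprintf("  %-20s {%s}\n", nm, paste(x$classes[[nm]], collapse = "")))
  }
  if (length(x$partition_groups) > 0) {
    cat("partition groups:",
        paste(vapply(x$partition_groups, paste, "", collapse = "+"),
              collapse = "; "), "\n")
  }
  invisible(x)
}
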