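#' Candidate O-GlcNAcylation sites of a sequence
#'
#' Every serine or threonine position is a candidate site.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet (plus X).
#' @return Ascending integer vector of 1-based S/T positions (empty for an
#'   empty sequence).
#' @export
extract_candidate_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "")[[1]]
  which(chars %in% c("S", "T"))
}

#' Build the +/-N sequence window around a site
#'
#' Returns the `2N+1`-character window centered on the site; positions that
#' fall outside the sequence are padded with `-`.
#'
#' @param sequence Amino-acid string.
#' @param site 1-based position; must hold S or T.
#' @param n_flank Half-width N (>= 0); the window covers positions
#'   `site - N ... site + N`.
#' @return Character scalar of length `2 * n_flank + 1`.
#' @export
build_window <- function(sequence, site, n_flank) {
  stopifnot(n_flank >= 0)
  chars <- strsplit(sequence, "")[[1]]
  if (site < 1 || site > length(chars)) abort("site out of sequence range")
  if (!chars[site] %in% c("S", "T")) {
    abort(sprintf("site %d holds '%s', not S/T", site, chars[site]))
  }
  idx <- (site - n_flank):(site + n_flank)
  w <- ifelse(idx >= 1 & idx <= length(chars), chars[pmax(idx, 1)], PAD_CHAR)
  paste(w, collapse = "")
}

#' One-hot encode a sequence window
#'
#' Each non-pad window character becomes a binary indicator row over the
#' alphabet; pad characters (and the unknown residue X) encode as all-zero
#' rows, so the number of 1-entries equals the number of real residues in
#' the window.
#'
#' @param window Window string (e.g. from [build_window()]).
#' @param alphabet Ordered alphabet defining the 20 columns.
#' @return Binary matrix, `nchar(window)` rows x `length(alphabet)` columns,
#'   with columns named `aa_<letter>`.
#' @export
one_hot_encode <- function(window, alphabet = AA_ALPHABET) {
  chars <- strsplit(window, "")[[1]]
  bad <- setdiff(chars, c(alphabet, PAD_CHAR, "X"))
  if (length(bad) > 0) {
    abort(sprintf("window contains characters outside the alphabet: %s",
                  paste(unique(bad), collapse = ",")))
  }
  m <- matrix(0, nrow = length(chars), ncol = length(alphabet),
              dimnames = list(NULL, paste0("aa_", alphabet)))
  hit <- match(chars, alphabet)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case amino-acid strings; names
#'   are the first whitespace-delimited token of each header.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  setNames(toupper(vapply(fa, function(s) as.character(s)[1], "")),
           vapply(fa, function(s) attr(s, "name"), ""))
}
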